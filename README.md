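# dermatex

Multi-class skin-disease image classification from texture and shape, for
researchers who want a fully inspectable, dependency-light reference
implementation of a dual-branch (image + handcrafted-feature) pipeline —
including its enhancement stage, descriptors, training loop, and
explainability — that runs and tests end to end on synthetic data, offline.

## What it implements

**Enhancement (ICTEF).** Three filter arms — double-stage Gaussian
(σ = 1, 3×3), locally adaptive 3×3 Wiener, and CLAHE followed by an exact
3×3 median — are each decomposed with a 3-level periodized db2 discrete
wavelet transform; corresponding subbands are fused by their arithmetic
mean

&nbsp;&nbsp;&nbsp;&nbsp;A_m = (A_G + A_W + A_M)/3,&nbsp; likewise H_m, V_m, D_m at every level,

and the inverse transform reconstructs the enhanced channel.

**Descriptors.** On the (enhanced) grayscale image:

- GLCM (8 levels, offset (1, 0°), symmetric): contrast Σ(i−j)²P_ij,
  correlation, energy ΣP², homogeneity ΣP/(1+|i−j|), autocorrelation
  Σij·P, entropy −ΣP ln P — 6 values;
- four-directional LBP: 3-bit codes from the top/bottom/left/right neighbor
  triples of each 3×3 window, four 8-bin histograms — 32 values;
- HOG: 8×8-px cells, 9 unsigned orientation bins, 2×2-cell blocks at 50%
  overlap, L2 normalization — 34,596 values at 256×256.

**Classifier (SDNet).** A 2D CNN on the RGB image and a 1D CNN on the
feature vector, each 3 × [Conv → ReLU → BatchNorm → MaxPool/2] with
64/128/256 filters, flattened, concatenated, and fed to a fully connected
softmax head; trained with Adam (lr 0.001, step decay ×0.5), stratified
70:30 split. The convolution engine is written in base-R matrix algebra —
no deep-learning framework required. Grad-CAM heatmaps attach to the last
2D conv block; metrics include per-class/macro/micro precision-recall-F1
and stratified k-fold cross-validation.

**Synthetic data.** A seeded generator of class-separable textured images
(Gaussian random fields plus irregular elliptical lesions) stands in for a
dermatology archive, so the whole pipeline is testable without any
download.

## Worked example

```r
library(dermatex)

ds <- generate_dataset(per_class = 40, size = c(32, 32), seed = 1)
feats <- extract_feature_matrix(ds$images)
cfg <- sdnet_config(num_classes = 5, image_size = c(32, 32),
                    vector_length = ncol(feats))
fit <- sdnet(ds$images, feats, ds$labels, config = cfg,
             epochs = 20, batch_size = 32, decay_every = 10,
             split = 0.7, seed = 1)
print(fit)
#> Dual-branch convolutional skin-image classifier
#>   branches: 2d + 1d
#>   classes:  acne, lupus, melanoma, urticaria_hives, herpes_hpv
#>   trainable parameters: 574,213
#>   trained 20 epochs; final loss 0.0000, train accuracy 1.000
#>   held-out accuracy: 0.983 (n = 60)
```

The held-out accuracy is measured on the stratified 30% the optimizer never
saw; at these well-separated synthetic conditions the fused model recovers
the five generative classes almost perfectly. Architecture accounting for
the published-table configuration:

```r
tab <- sdnet_param_table(table2_config())
attr(tab, "flatten")
#>      2d      1d
#>  262144 1106944
```

Explaining a prediction:

```r
img <- generate_image(default_texture_specs()$melanoma, size = c(32, 32), seed = 7)
cam <- grad_cam(fit, img, features = extract_features(img),
                target_class = "melanoma")
write_gradcam_overlay(cam, img, "melanoma_cam.png")
```

A command-line front end wrapping these functions ships in
`inst/cli/dermatex` (subcommands `synth`, `enhance`, `features`, `train`,
`evaluate`, `explain`, `run`).

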