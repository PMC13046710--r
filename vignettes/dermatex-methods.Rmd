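---
title: "Texture- and shape-based skin disease classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture- and shape-based skin disease classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermatex)
```

dermatex classifies multi-class skin-disease images with a dual-branch
convolutional network: a 2D branch that reads the (optionally enhanced) RGB
image, and a 1D branch that reads a handcrafted vector of texture and shape
descriptors. This vignette explains each stage, the parameters that matter,
and the design decisions taken where more than one reasonable choice
existed.

## Image enhancement by wavelet mean-fusion

The enhancement stage runs three complementary filter arms over each
channel:

1. **double-stage Gaussian** — the same normalized kernel (default
   `sigma = 1` px, 3×3 window) applied twice; a stronger low-pass that
   suppresses high-frequency noise;
2. **adaptive Wiener** — pixelwise shrinkage toward the local 3×3 mean with
   gain `(v - nu) / v`, where `v` is the local variance and the noise power
   `nu` is estimated as the mean local variance; smooths flat regions while
   sparing edges;
3. **CLAHE + median** — contrast-limited adaptive histogram equalization
   (8×8 tiles, 256 bins, clip limit 0.01 of the tile mass) followed by an
   exact 3×3 median; raises local contrast and removes impulse noise. The
   clip limit is applied fractionally (`clip * n_tile` per bin, with the
   clipped mass redistributed uniformly), so it stays effective even for
   tiles too small for any integer count to exceed it — an integer floor of
   one count would disable the limiter on small tiles and turn the arm into
   an error-amplifying full equalization.

Each arm is decomposed with a 3-level periodized db2 discrete wavelet
transform, corresponding subbands (approximation and the horizontal /
vertical / diagonal details at *every* level) are averaged elementwise, and
the inverse transform reconstructs the channel, clipped to [0, 1].

Numerical choices:

* **Periodized boundaries.** They make the transform orthogonal with exactly
  halved subbands, so the round-trip is exact to machine precision
  (the test suite asserts 1e-8). Dimensions not divisible by `2^levels`
  are mirror-padded and cropped back.
* **Fusion at all levels.** The mean-fusion rule is stated per subband; the
  inverse transform needs detail coefficients at every level, so details at
  levels 1..J are fused the same way as the coarsest level. Any other
  reading leaves the reconstruction undefined.
* **CLAHE tile mappings are stored as corrections to the identity** and
  tiles with zero intensity range use the identity mapping. This makes the
  whole enhancement exactly idempotent on constant images, a property the
  test suite checks to 1e-6 — and the reason the package carries its own
  CLAHE and median rather than delegating to a generic image library (the
  available implementations quantize intensities internally).
* The three arms are computed per RGB channel because the 2D branch
  consumes three-channel images; fusing a luminance channel only would
  discard chromatic information the network can use.

## Handcrafted descriptors

All descriptors are computed on the grayscale image (luma weights
0.299/0.587/0.114) — the enhanced grayscale whenever the preprocessing arm
is enabled, so both network branches see the same image content.

**Co-occurrence statistics.** Intensities are uniformly quantized to
`levels = 8` gray levels; pairs at displacement `(distance = 1, angle = 0°)`
are counted, symmetrized, and normalized into `P`. Six statistics are
reported: contrast, correlation, energy, homogeneity, autocorrelation, and
entropy (natural log, zero cells contribute nothing). The level count,
distance and angle are configurable; the defaults are the smallest standard
choice consistent with the magnitudes commonly reported for 8-level
matrices. Correlation uses the row/column marginal standard deviations in
the denominator, which keeps it in [-1, 1] for asymmetric matrices and
reduces to the variance form on symmetric ones. A constant image has zero
marginal variance; correlation is then reported as 1 (a constant field is
perfectly self-similar) with a warning rather than an error, so batch
extraction never aborts.

**Four-directional local binary patterns.** The classic 8-neighbor LBP
thresholds every 3×3 neighbor strictly against the center (ties give bit 0)
and packs a byte, p1 as the most significant bit; its histogram has 256
bins. The reduced descriptor splits the window into top (p1, p2, p3),
bottom (p6, p7, p8), left (p1, p4, p6), and right (p3, p5, p8) triples,
giving four 3-bit code maps (values 0–7) and four 8-bin histograms,
concatenated in U, B, L, R order: 32 features instead of 256. Design
choices: the first listed neighbor is the most significant bit (the
membership of each triple is fixed, the bit order is not — any fixed order
is valid and this one is tested); histograms are raw counts over the whole
image; codes are computed for interior pixels only, so no invented padding
values enter the histograms. The codes are invariant to intensity shifts
and positive rescaling, but not to image rotation.

**Histograms of oriented gradients.** Gradients use the [-1 0 1] kernel and
its transpose with replicate borders; orientation is unsigned, over
[0°, 180°) in 9 bins of 20°, and each pixel votes its magnitude into the
two nearest bin centers (circular linear interpolation). Cells are 8×8 px,
blocks are 2×2 cells advanced by 1 cell (50% overlap), each block is
L2-normalized with an epsilon guard of 1e-6 and no clipping. On a 256×256
image this yields a 31×31 block grid × 36 values = 34,596 features — the
count that fixes the geometry: it is reproduced only with a one-cell block
stride. The orientation at zero magnitude is defined as 0°; its vote weight
is zero, so the choice is inert.

The full handcrafted vector is `[6 GLCM | 32 ILBP | 34,596 HOG] = 34,634`
values at 256×256. The feature matrix carries its extraction configuration,
and a fitted model refuses feature matrices whose configuration differs
from the one it was trained with.

## The dual-branch network

Both branches stack three blocks of convolution (stride 1, same padding) →
ReLU → batch normalization → max pooling (stride 2, floor on odd lengths);
filters are 64, 128, 256. The 2D branch flattens to `(H/8)(W/8)·256`
values, the 1D branch to `floor(L/8)·256`; the two flattened vectors are
concatenated into a single fully connected softmax layer.

* Same padding is forced by the published per-layer output sizes, which
  equal the input sizes for every convolution; the floor rule on odd pooled
  lengths is forced by the printed 8,649 → 4,324 transition.
* The default 1D input is the full 34,634-length concatenation; a
  compatibility mode (`table2_config()`) reproduces the published
  accounting exactly: a 34,596-long input (HOG alone), four output units,
  and a biasless head — giving flatten lengths 262,144 and 1,106,944,
  concatenation 1,369,088, and a 5,476,352-parameter head. Both
  configurations are supported because the published description and the
  published table disagree; the accounting tests run in compatibility mode,
  everything else defaults to the full vector and five classes.
* Parameter counting is standard dense-across-channels convolution
  (`k·Cin·Cout + Cout`); the published counts for the second and third 1D
  convolutions ignore input channels and are not reproduced.
* Training follows the published hyperparameters: Adam at learning rate
  0.001 with a stepwise decay ×0.5 (the published "decay rate 0.5" names no
  schedule; a step schedule — every 50 epochs at full scale, scaled
  proportionally at reduced scale — is the implemented reading and is
  configurable), cross-entropy loss, stratified 70:30 split.
* Handcrafted features are standardized per dimension (z-score fitted on
  the training split only) before the 1D branch. Raw co-occurrence
  statistics (~1), pattern counts (~10³) and gradient histograms (~10⁻¹)
  differ by orders of magnitude, and the first batch-normalization layer
  alone converges poorly from such inputs. This is an engineering choice
  the published method is silent about; it can be disabled.
* Batch normalization follows ReLU, matching the published layer order;
  running moments (momentum 0.9) drive inference mode, whose backward pass
  is the fixed affine map.
* Convolution weights use He initialization; the softmax head is
  initialized at small scale (sd 0.01) so a freshly built model starts
  from near-zero logits and predicts close to the uniform distribution —
  large-scale head initialization would give every seed an arbitrary
  class bias driven by the positive mean of the pooled activations.
* Prediction takes the argmax, ties broken to the lowest class index.

The engine is written in base-R matrix algebra: convolutions are sums of
channel-mixing matrix products over shifted activations, so every step runs
on BLAS. Ablation configurations (`branches = "2d"` or `"1d"`) give the
single-branch baselines the experiment runner reports alongside the fused
model.

## Explainability

Grad-CAM attaches to the last 2D convolutional block: the gradient of the
target-class logit is taken with respect to the post-ReLU feature maps,
averaged spatially into channel weights, and the rectified weighted sum of
the maps is upsampled bilinearly and max-normalized. If the head assigns
the 2D branch zero weight, the map is identically zero — a property the
test suite asserts, along with proportionality to a single channel's
activation when the head attends to exactly that channel.

## Evaluation

Accuracy, per-class one-vs-rest precision/recall/F1, unweighted macro
means, and pooled micro precision/recall are all reported, because mixing
conventions is common: for single-label multiclass data micro recall
*equals* accuracy, while macro precision differs — reporting both labeled
avoids ambiguity. Zero-denominator classes yield 0 with a warning.
Stratified k-fold cross-validation reports per-fold accuracy, their mean,
sample standard deviation, and the normal-approximation interval
`mean ± 1.96·sd/√k`; this formula is the documented choice (published
cross-validation intervals are not exactly reproducible from their printed
means and standard deviations under any standard formula).

## The synthetic data generator

No image collection ships with the package; the generator stands in for a
dermatology archive so that every stage is testable offline. Each class is
a stationary Gaussian random field: white noise smoothed circularly at a
correlation length, scaled to a texture amplitude, offset by a base gray
level, optionally carrying an elliptical lesion whose radius is perturbed
sinusoidally (seeded phase) and whose interior is offset in intensity — a
shape signal for the gradient descriptors. All three channels derive from
one luminance field with small seeded chromatic offsets, so grayscale
descriptors remain consistent with the RGB input. Images are stored as
8-bit PNG; computation is floating point on [0, 1].

The five default classes emulate the qualitative descriptor orderings of
the diseases studied in the source domain — the smoothest class
(urticaria-like: amplitude 0.05, correlation length 3) has the lowest
contrast and highest correlation, the roughest (herpes-like: amplitude
0.40, length 1) the highest contrast; melanoma-like images carry a large
dark irregular lesion, acne-like a small one. Amplitudes are deliberately
well separated: the recovery experiment asks whether the pipeline can
recover class structure that is present by construction, not whether it
can match clinical difficulty. Degradations are controlled by
`noise_sigma` (additive Gaussian, applied per channel after the texture)
and `blur_sigma`.

What the generator does *not* emulate: hair, ruler marks, specular
highlights, vignetting, and the intra-class diversity of real archives.
Passing the recovery experiment therefore demonstrates that the
implementation is correct and the pipeline is learnable end to end — not
that the published clinical accuracies transfer.

## Reduced-scale study conditions

The recovery experiment runs at 32×32 resolution with 40 images per class
(5 classes, stratified 70:30 split), the full 64/128/256 filter stacks, 20
epochs of Adam at learning rate 0.001, batch 16–32, and decay ×0.5 every 10
epochs — a schedule proportional to the published 200-epoch/50-epoch one.
At this scale the handcrafted vector has 362 dimensions (6 + 32 + 324 HOG).
These sizes are the package's chosen test conditions: large enough that the
fused model reliably exceeds 95% held-out accuracy on clean well-separated
data, small enough that the whole experiment (including the with/without
enhancement comparison on noise-degraded data) runs in minutes on one CPU.

## Known limitations

* Only the db2 wavelet is provided; other families would need their filter
  pairs added.
* The engine trains small networks on small images efficiently but is not
  a GPU framework; published-scale training (256×256, 200 epochs, thousands
  of images) is out of its intended range.
* Alternative fusion rules (max, weighted), rotation-invariant pattern
  variants, multi-offset co-occurrence averaging, and data augmentation are
  deliberately out of scope.
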