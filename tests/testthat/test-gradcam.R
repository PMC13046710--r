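toy_2d_fit <- function(seed = 2) {
  # minimal trained-free model: initialized weights suffice for contracts
  cfg <- sdnet_config(num_classes = 3, image_size = c(16, 16),
                      vector_length = 16, conv2d_filters = c(4, 8, 8),
                      conv1d_filters = c(4, 8, 8), branches = "2d")
  init <- dermatex:::sdnet_init(cfg, seed = seed)
  structure(list(params = init$params, buffers = init$buffers, config = cfg,
                 classes = c("a", "b", "c"), history = NULL, scaling = NULL,
                 feature_config = NULL, test = NULL),
            class = "sdnet")
}

test_that("heatmaps satisfy the range and shape contract", {
  fit <- toy_2d_fit()
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  cam <- grad_cam(fit, img, target_class = "b")
  expect_true(all(cam$upsampled >= 0 & cam$upsampled <= 1))
  expect_equal(dim(cam$upsampled), c(16, 16))
  # conv3 runs after two pools (16 -> 8 -> 4); its post-ReLU maps, where
  # grad-cam attaches, are 4 x 4 -- the third pool comes after them
  expect_equal(dim(cam$raw), c(4, 4))
  expect_equal(cam$target_class, "b")
  expect_error(grad_cam(fit, img, target_class = 9), "out of range")
  expect_error(grad_cam(fit, img, target_class = "zz"), "unknown class")
})

test_that("a head attending to one channel gives a map proportional to it", {
  fit <- toy_2d_fit(seed = 6)
  hw <- 2 * 2; nch <- 8
  # make the last batch norm the identity so pooled activations pass through
  fit$params$`c2dbn3.gamma` <- rep(1, nch); fit$params$`c2dbn3.beta` <- rep(0, nch)
  fit$buffers$`c2dbn3.rm` <- rep(0, nch); fit$buffers$`c2dbn3.rv` <- rep(1 - 1e-5, nch)
  set.seed(8)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  # pick a channel with a live post-ReLU activation on this input
  fw <- dermatex:::sdnet_forward(fit$params, fit$buffers, fit$config,
                                 array(img, c(16, 16, 3, 1)), NULL,
                                 training = FALSE, keep_cache = TRUE)
  acts <- array(fw$fwd2$caches[[3]]$relu_out, c(4, 4, nch))
  chan <- which.max(apply(acts, 3, max))
  # rebuild the head so class 1 reads exactly that conv channel
  fit$params$fc.W[] <- 0
  rows <- (chan - 1) * hw + seq_len(hw)   # spatial-first flatten layout
  fit$params$fc.W[rows, 1] <- 1
  cam <- grad_cam(fit, img, target_class = 1)
  # the pooled gradient weight is positive, so the normalized map equals the
  # channel's activation normalized to unit maximum
  ref <- acts[, , chan] / max(acts[, , chan])
  expect_equal(cam$raw, ref, tolerance = 1e-10)
  expect_equal(length(cam$weights), nch)
  expect_true(all(cam$weights[-chan] == 0))
})

test_that("a detached head produces an identically zero heatmap", {
  fit <- toy_2d_fit(seed = 3)
  fit$params$fc.W[] <- 0   # no gradient flows into the conv stack
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  cam <- grad_cam(fit, img, target_class = 2)
  expect_true(all(cam$raw == 0))
  expect_true(all(cam$upsampled == 0))
})

test_that("trained models localize the lesion of synthetic melanoma images", {
  fx <- recovery_fixture()
  spec <- default_texture_specs()$melanoma
  inside <- outside <- numeric(10)
  for (i in 1:10) {
    img <- generate_image(spec, size = c(32, 32), seed = 9000 + i)
    feats <- extract_features(img)
    cam <- grad_cam(fx$fit, img, features = feats, target_class = "melanoma")
    mask <- dermatex:::lesion_mask(32, 32, spec$lesion, phase = 0) > 0.5
    inside[i] <- mean(cam$upsampled[mask])
    outside[i] <- mean(cam$upsampled[!mask])
  }
  expect_gt(mean(inside), mean(outside))
})

test_that("grad-cam raw maps match the last conv grid size", {
  fit <- toy_2d_fit()
  img <- array(0.5, c(16, 16, 3))
  cam <- grad_cam(fit, img, target_class = 1)
  expect_s3_class(cam, "grad_cam")
  expect_output(print(cam), "Grad-CAM")
})
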