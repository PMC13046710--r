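# Shared fixtures. Expensive artifacts (the trained recovery models) are
# built lazily once per session and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

random_gray <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Two-class texture specs used by small end-to-end tests.
tiny_specs <- function() {
  list(
    smooth = class_texture_spec("smooth", base_gray = 0.7,
                                texture_amplitude = 0.05,
                                correlation_length = 3),
    rough = class_texture_spec("rough", base_gray = 0.4,
                               texture_amplitude = 0.35,
                               correlation_length = 1)
  )
}

# Reduced-scale recovery experiment shared by the acceptance and Grad-CAM
# tests: clean well-separated five-class data, 40 images per class at
# 32 x 32, fused model trained on a stratified 70% split.
recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  ds <- generate_dataset(per_class = 40, size = c(32, 32),
                         noise_sigma = 0, seed = 1)
  feats <- extract_feature_matrix(ds$images)
  cfg <- sdnet_config(num_classes = 5, image_size = c(32, 32),
                      vector_length = ncol(feats))
  fit <- sdnet(ds$images, feats, ds$labels, config = cfg, epochs = 20,
               batch_size = 32, decay_every = 10, split = 0.7, seed = 1)
  .fixture_env$recovery <- list(ds = ds, feats = feats, fit = fit)
  .fixture_env$recovery
}

# Naive reference implementations (oracles), written independently of the
# vectorized package code.

naive_glcm_stats <- function(P) {
  n <- nrow(P)
  ct <- en <- hm <- ac <- et <- 0
  mu_i <- mu_j <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    p <- P[i + 1, j + 1]
    mu_i <- mu_i + i * p; mu_j <- mu_j + j * p
  }
  v_i <- v_j <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    p <- P[i + 1, j + 1]
    v_i <- v_i + (i - mu_i)^2 * p; v_j <- v_j + (j - mu_j)^2 * p
  }
  cr <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    p <- P[i + 1, j + 1]
    ct <- ct + (i - j)^2 * p
    en <- en + p^2
    hm <- hm + p / (1 + abs(i - j))
    ac <- ac + i * j * p
    if (p > 0) et <- et - p * log(p)
    cr <- cr + (i - mu_i) * (j - mu_j) * p
  }
  cr <- cr / sqrt(v_i * v_j)
  c(contrast = ct, correlation = cr, energy = en, homogeneity = hm,
    autocorrelation = ac, entropy = et)
}

naive_ilbp <- function(img) {
  h <- nrow(img); w <- ncol(img)
  U <- B <- L <- R <- matrix(0L, h - 2, w - 2)
  for (y in 2:(h - 1)) for (x in 2:(w - 1)) {
    c0 <- img[y, x]
    p <- c(img[y - 1, x - 1], img[y - 1, x], img[y - 1, x + 1],
           img[y, x - 1], img[y, x + 1],
           img[y + 1, x - 1], img[y + 1, x], img[y + 1, x + 1])
    bit <- as.integer(p > c0)
    U[y - 1, x - 1] <- 4L * bit[1] + 2L * bit[2] + bit[3]
    B[y - 1, x - 1] <- 4L * bit[6] + 2L * bit[7] + bit[8]
    L[y - 1, x - 1] <- 4L * bit[1] + 2L * bit[4] + bit[6]
    R[y - 1, x - 1] <- 4L * bit[3] + 2L * bit[5] + bit[8]
  }
  list(U = U, B = B, L = L, R = R)
}

naive_median3_interior <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (y in 2:(h - 1)) for (x in 2:(w - 1))
    out[y, x] <- median(img[(y - 1):(y + 1), (x - 1):(x + 1)])
  out
}
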