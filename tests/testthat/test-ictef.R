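test_that("Gaussian kernel equals the normalized density on the window grid", {
  k <- gaussian_kernel(sigma = 1, window = 3)
  ref <- outer(-1:1, -1:1, function(y, x) exp(-(x^2 + y^2) / 2))
  ref <- ref / sum(ref)
  expect_equal(k, ref, tolerance = 1e-15)
  expect_equal(sum(k), 1, tolerance = 1e-15)
  # impulse response reproduces the kernel
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  resp <- gaussian_filter(imp, 1, 3)[2:4, 2:4]
  expect_equal(resp, ref, tolerance = 1e-15)
  expect_error(gaussian_kernel(1, 4), "odd")
})

test_that("Gaussian filtering preserves constants and reduces noise variance", {
  expect_equal(gaussian_filter(matrix(0.42, 20, 20)),
               matrix(0.42, 20, 20), tolerance = 1e-14)
  x <- random_gray(64, 64, seed = 9)
  expect_lt(var(as.vector(gaussian_filter(x))), var(as.vector(x)))
})

test_that("all three filter arms preserve constant images", {
  cimg <- matrix(0.37, 32, 32)
  arms <- filter_arms(cimg)
  for (a in arms) expect_equal(a, cimg, tolerance = 1e-12)
})

test_that("median arm restores a sparsely corrupted constant image", {
  set.seed(21)
  img <- matrix(0.5, 24, 24)
  hits <- sample(length(img), 20)  # < 1/9 density per 3x3 window on average
  img[hits] <- rep(c(0, 1), 10)
  med <- median_filter3(img)
  ref <- naive_median3_interior(img)
  interior <- !is.na(ref)
  expect_equal(med[interior], ref[interior], tolerance = 0)
  # interior windows containing at most 4 corrupted pixels recover 0.5
  expect_gt(mean(med[interior] == 0.5), 0.95)
})

test_that("each arm denoises a corrupted smooth ramp", {
  set.seed(31)
  h <- 48; w <- 48
  ramp <- matrix(rep(seq(0.2, 0.8, length.out = w), each = h), h, w)
  noisy <- ramp + matrix(rnorm(h * w, 0, 0.08), h, w)
  noisy[noisy < 0] <- 0; noisy[noisy > 1] <- 1
  mse <- function(a) mean((a - ramp)^2)
  arms <- filter_arms(noisy)
  expect_lt(mse(arms$gauss), mse(noisy))
  expect_lt(mse(arms$wiener), mse(noisy))
  expect_lt(mse(arms$median), mse(noisy))
})

test_that("wavelet decomposition of a constant has vanishing details", {
  sb <- dwt_decompose(matrix(0.6, 32, 32), "db2", 3)
  for (j in 1:3) for (b in c("h", "v", "d"))
    expect_lt(max(abs(sb$details[[j]][[b]])), 1e-10)
  # periodized orthogonal lowpass scales a constant by 2 per 2D level
  expect_equal(mean(sb$approximation), 0.6 * 2^3, tolerance = 1e-10)
  expect_error(dwt_decompose(matrix(0, 32, 32), "sym4", 3), "unsupported")
})

test_that("wavelet transform is orthogonal and perfectly invertible", {
  x <- random_gray(64, 64, seed = 13)
  sb <- dwt_decompose(x, "db2", 3)
  expect_lt(max(abs(idwt_reconstruct(sb) - x)), 1e-8)
  energy <- sum(sb$approximation^2) +
    sum(unlist(lapply(sb$details, function(d)
      sum(d$h^2) + sum(d$v^2) + sum(d$d^2))))
  expect_equal(energy, sum(x^2), tolerance = 1e-6)
})

test_that("level-1 db2 coefficients match the frozen reference decomposition", {
  # reference values computed with an independent wavelet implementation
  x <- matrix(0, 8, 8)
  for (i in 0:7) for (j in 0:7)
    x[i + 1, j + 1] <- sin(1 + i * 0.7) * cos(2 + j * 0.9) + 0.1 * (i + 1) * (j + 1) / 64
  cA <- matrix(c(-0.406724753298725, -0.733008103562811, 0.449448074411593, 1.02047519025282, -0.784338935519383, -1.37549343289536, 0.774100390498131, 1.79258939213774, 0.57855153734514, 0.949709708091879, -0.413059682269609, -1.02332329462735, 0.601192159739969, 0.961706809682009, -0.367970351046314, -0.94743003471941), 4, 4)
  cH <- matrix(c(-0.25159995935492, -0.0339597374119635, 0.174166214647926, 0.293822446687243, -0.453986465603105, -0.0623725072417822, 0.319884201477206, 0.50935814398546, 0.281664811348275, 0.0406940679619478, -0.208703962859885, -0.278088321686994, 0.272051235638036, 0.0402257353845057, -0.206302068192093, -0.251107272302293), 4, 4)
  cV <- matrix(c(-0.192729005568902, -0.32437894230969, 0.157090713964183, 0.377784667641641, -0.0539665168221436, -0.0928527316110155, 0.0489099028026134, 0.115101663792611, 0.284930932668576, 0.490241301026416, -0.258233160909874, -0.60771060182036, -0.224371268784433, -0.413002142144393, 0.268956430678382, 0.60272881138505), 4, 4)
  cD <- matrix(c(-0.100395495573188, -0.0142118964081361, 0.0728872597083609, 0.104685870514832, -0.0297703671704683, -0.00414512233094751, 0.0212587116583353, 0.0323561853371571, 0.157180766580194, 0.0218853029865659, -0.112241161683727, -0.170833298285626, -0.145876487028263, -0.0194411061865147, 0.0997058319974173, 0.175079592742951), 4, 4)
  sb <- dwt_decompose(x, "db2", 1)
  expect_equal(sb$approximation, cA, tolerance = 1e-12)
  expect_equal(sb$details[[1]]$h, cH, tolerance = 1e-12)
  expect_equal(sb$details[[1]]$v, cV, tolerance = 1e-12)
  expect_equal(sb$details[[1]]$d, cD, tolerance = 1e-12)
})

test_that("mean fusion is the elementwise mean and is symmetric and linear", {
  x <- random_gray(16, 16, seed = 3)
  sb <- dwt_decompose(x, "db2", 2)
  expect_equal(mean_fuse(sb, sb, sb), sb, tolerance = 1e-14)
  scale_sb <- function(s, f) {
    s$approximation <- f * s$approximation
    for (j in seq_len(s$levels)) for (b in c("h", "v", "d"))
      s$details[[j]][[b]] <- f * s$details[[j]][[b]]
    s
  }
  a <- scale_sb(sb, 0.3); b <- scale_sb(sb, 0.6); c <- scale_sb(sb, 0.9)
  fused <- mean_fuse(a, b, c)
  expect_equal(fused, scale_sb(sb, 0.6), tolerance = 1e-13)
  expect_equal(mean_fuse(c, a, b), fused, tolerance = 1e-14)
  wrong <- dwt_decompose(random_gray(16, 16, 4), "db2", 1)
  expect_error(mean_fuse(sb, sb, wrong), "levels|size")
})

test_that("zeroed detail subbands reconstruct the approximation-only image", {
  x <- random_gray(32, 32, seed = 8)
  sb <- dwt_decompose(x, "db2", 2)
  zero <- sb
  for (j in 1:2) for (b in c("h", "v", "d"))
    zero$details[[j]][[b]] <- zero$details[[j]][[b]] * 0
  ref <- sb
  for (j in 1:2) for (b in c("h", "v", "d"))
    ref$details[[j]][[b]] <- matrix(0, nrow(ref$details[[j]][[b]]),
                                    ncol(ref$details[[j]][[b]]))
  expect_equal(idwt_reconstruct(zero), idwt_reconstruct(ref), tolerance = 1e-14)
})

test_that("enhancement is idempotent on constants and preserves shape", {
  const <- array(0.81, c(16, 16, 3))
  expect_equal(ictef_enhance(const), const, tolerance = 1e-6)
  img <- generate_image(default_texture_specs()$acne, size = c(20, 24), seed = 2)
  out <- ictef_enhance(img)  # 20 x 24 is not divisible by 8: exercises padding
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("enhancement reduces the error of noise-degraded synthetic images", {
  specs <- default_texture_specs()
  mse_enh <- mse_noisy <- numeric(20)
  for (i in 1:20) {
    spec <- specs[[((i - 1) %% 5) + 1]]
    clean <- generate_image(spec, size = c(32, 32), noise_sigma = 0, seed = 400 + i)
    noisy <- generate_image(spec, size = c(32, 32), noise_sigma = 0.1, seed = 400 + i)
    enh <- ictef_enhance(noisy)
    mse_noisy[i] <- mean((noisy - clean)^2)
    mse_enh[i] <- mean((enh - clean)^2)
  }
  expect_lt(mean(mse_enh), mean(mse_noisy))
})
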