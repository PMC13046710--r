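# Image enhancement stage: three filter arms (double-stage Gaussian;
# locally adaptive Wiener; CLAHE followed by median) fused by per-subband
# mean in a 3-level periodized db2 wavelet decomposition.

# Shift a matrix by (dy, dx) with replicate (clamped) borders.
shift_replicate <- function(x, dy, dx) {
  h <- nrow(x); w <- ncol(x)
  ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
  x[ri, ci, drop = FALSE]
}

# 3x3 (or larger odd) correlation with replicate borders.
conv_replicate <- function(x, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ry <- (kh - 1L) / 2L; rx <- (kw - 1L) / 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    k <- kernel[i, j]
    if (k != 0) out <- out + k * shift_replicate(x, i - 1L - ry, j - 1L - rx)
  }
  out
}

#' Discrete Gaussian kernel
#'
#' Evaluates the isotropic Gaussian density on the integer offset grid of an
#' odd window and normalizes it to sum to one, so filtering preserves
#' constants exactly.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param window odd kernel side length (>= 3).
#' @return a `window` x `window` matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma = 1, window = 3) {
  if (sigma <= 0) stop("sigma must be > 0")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  r <- (window - 1L) / 2L
  d <- seq(-r, r)
  g <- outer(d, d, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

#' Gaussian low-pass filter
#'
#' @param image numeric matrix on \[0, 1\].
#' @param sigma,window as in [gaussian_kernel()].
#' @return filtered matrix of the same size (replicate borders).
#' @export
gaussian_filter <- function(image, sigma = 1, window = 3) {
  assert_gray(image)
  conv_replicate(image, gaussian_kernel(sigma, window))
}

#' Locally adaptive Wiener filter
#'
#' Pixelwise Wiener shrinkage toward the local mean using local first and
#' second moments over an odd window; the noise power defaults to the mean
#' of the local variances. Where the local variance falls below the noise
#' estimate the output is the local mean.
#'
#' @param image numeric matrix.
#' @param window odd window side (default 3).
#' @param noise optional noise power; estimated from the image when `NULL`.
#' @return filtered matrix of the same size.
#' @export
wiener_filter <- function(image, window = 3, noise = NULL) {
  assert_gray(image)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  box <- matrix(1 / window^2, window, window)
  m <- conv_replicate(image, box)
  v <- pmax(conv_replicate(image^2, box) - m^2, 0)
  if (is.null(noise)) noise <- mean(v)
  gain <- ifelse(v > noise & v > 0, (v - noise) / pmax(v, .Machine$double.eps), 0)
  m + gain * (image - m)
}

# Exact 3x3 median via the median-of-sorted-triples network (vectorized).
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

#' Median filter (3x3)
#'
#' Exact 3x3 median at every pixel (replicate borders), computed with a
#' vectorized selection network rather than per-pixel sorting.
#'
#' @param image numeric matrix.
#' @return filtered matrix of the same size.
#' @export
median_filter3 <- function(image) {
  assert_gray(image)
  p <- vector("list", 9); k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    p[[k]] <- shift_replicate(image, dy, dx)
  }
  lo <- hi <- md <- vector("list", 3)
  for (t in 1:3) {
    i <- (t - 1L) * 3L
    a <- p[[i + 1]]; b <- p[[i + 2]]; c <- p[[i + 3]]
    lo[[t]] <- pmin(a, b, c)
    hi[[t]] <- pmax(a, b, c)
    md[[t]] <- med3(a, b, c)
  }
  med3(pmax(lo[[1]], lo[[2]], lo[[3]]),
       med3(md[[1]], md[[2]], md[[3]]),
       pmin(hi[[1]], hi[[2]], hi[[3]]))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit and bilinear
#' interpolation between neighboring tile mappings. Tiles with zero
#' intensity range use the identity mapping, so constant images pass
#' through unchanged.
#'
#' @param image numeric matrix on \[0, 1\].
#' @param tiles number of tiles per side (default 8).
#' @param bins histogram bins per tile (default 256).
#' @param clip clip limit as a fraction of the tile's pixel count
#'   (default 0.01); histogram mass above `clip * n_tile` per bin is
#'   redistributed uniformly.
#' @return equalized matrix on \[0, 1\].
#' @export
clahe_filter <- function(image, tiles = 8, bins = 256, clip = 0.01) {
  assert_gray(image)
  h <- nrow(image); w <- ncol(image)
  tiles <- as.integer(tiles)
  ty <- pmin(tiles, h); tx <- pmin(tiles, w)
  x <- clip01(image)
  bin <- pmin(floor(x * bins), bins - 1L) + 1L                # 1..bins
  ye <- round(seq(0, h, length.out = ty + 1)); xe <- round(seq(0, w, length.out = tx + 1))
  yt <- findInterval(seq_len(h), ye[-1] + 0.5) + 1L           # tile row of each pixel
  xt <- findInterval(seq_len(w), xe[-1] + 0.5) + 1L
  ntile <- ty * tx
  # per-tile mapping stored as a correction to the identity, so flat tiles
  # (zero intensity range) leave their pixels exactly unchanged
  ident <- (seq_len(bins) - 0.5) / bins
  maps <- matrix(0, bins, ntile)
  cy <- (ye[-1] + ye[-(ty + 1)] + 1) / 2                      # tile center rows
  cx <- (xe[-1] + xe[-(tx + 1)] + 1) / 2
  for (tyi in seq_len(ty)) for (txi in seq_len(tx)) {
    rows <- (ye[tyi] + 1):ye[tyi + 1]; colsx <- (xe[txi] + 1):xe[txi + 1]
    vt <- x[rows, colsx]
    if (max(vt) - min(vt) <= 0) next                          # identity for flat tiles
    bt <- bin[rows, colsx]
    n <- length(bt)
    hst <- tabulate(bt, bins)
    # fractional clip limit: mass above clip * n per bin is redistributed
    # uniformly, so the limit stays effective even for small tiles whose
    # per-bin counts never exceed 1
    lim <- clip * n
    excess <- sum(pmax(hst - lim, 0))
    hst <- pmin(hst, lim) + excess / bins
    cdf <- cumsum(hst) / n
    maps[, (txi - 1L) * ty + tyi] <- cdf - ident
  }
  # bilinear interpolation between the four surrounding tile mappings
  fy <- if (ty == 1L) rep(1, h) else
    stats::approx(cy, seq_len(ty), xout = seq_len(h), rule = 2)$y
  fx <- if (tx == 1L) rep(1, w) else
    stats::approx(cx, seq_len(tx), xout = seq_len(w), rule = 2)$y
  y0 <- pmin(pmax(floor(fy), 1L), ty); y1 <- pmin(y0 + 1L, ty)
  x0 <- pmin(pmax(floor(fx), 1L), tx); x1 <- pmin(x0 + 1L, tx)
  wy <- fy - floor(fy); wx <- fx - floor(fx)
  Y0 <- matrix(y0, h, w); Y1 <- matrix(y1, h, w)
  X0 <- matrix(x0, h, w, byrow = TRUE); X1 <- matrix(x1, h, w, byrow = TRUE)
  WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)
  g <- function(TY, TX) matrix(maps[cbind(as.vector(bin),
                                          as.vector((TX - 1L) * ty + TY))], h, w)
  corr <- (1 - WY) * ((1 - WX) * g(Y0, X0) + WX * g(Y0, X1)) +
          WY       * ((1 - WX) * g(Y1, X0) + WX * g(Y1, X1))
  clip01(x + corr)
}

#' ICTEF configuration
#'
#' @param sigma Gaussian arm standard deviation (default 1).
#' @param gauss_window Gaussian window side (default 3).
#' @param wiener_window Wiener window side (default 3).
#' @param clahe_tiles,clahe_bins,clahe_clip CLAHE parameters.
#' @param wavelet wavelet name (default `"db2"`).
#' @param levels decomposition levels (default 3).
#' @return a list of class `ictef_config`.
#' @export
ictef_config <- function(sigma = 1, gauss_window = 3, wiener_window = 3,
                         clahe_tiles = 8, clahe_bins = 256, clahe_clip = 0.01,
                         wavelet = "db2", levels = 3) {
  structure(list(sigma = sigma, gauss_window = gauss_window,
                 wiener_window = wiener_window, clahe_tiles = clahe_tiles,
                 clahe_bins = clahe_bins, clahe_clip = clahe_clip,
                 wavelet = wavelet, levels = levels),
            class = "ictef_config")
}

#' The three enhancement filter arms
#'
#' Computes the double-stage Gaussian arm (the same kernel applied twice),
#' the adaptive Wiener arm, and the CLAHE-then-median arm. All outputs are
#' clipped to \[0, 1\].
#'
#' @param image numeric matrix on \[0, 1\], at least 3x3.
#' @param config an [ictef_config()].
#' @return a list with `gauss`, `wiener`, `median` matrices.
#' @export
filter_arms <- function(image, config = ictef_config()) {
  assert_gray(image)
  if (any(dim(image) < 3L)) stop("image must be at least 3x3")
  g1 <- gaussian_filter(image, config$sigma, config$gauss_window)
  arm_g <- gaussian_filter(g1, config$sigma, config$gauss_window)
  arm_w <- wiener_filter(image, config$wiener_window)
  arm_m <- median_filter3(clahe_filter(image, config$clahe_tiles,
                                       config$clahe_bins, config$clahe_clip))
  list(gauss = clip01(arm_g), wiener = clip01(arm_w), median = clip01(arm_m))
}

ictef_enhance_gray <- function(gray, config) {
  arms <- filter_arms(gray, config)
  div <- 2L^config$levels
  h <- nrow(gray); w <- ncol(gray)
  ph <- ceiling(h / div) * div - h
  pw <- ceiling(w / div) * div - w
  pad <- function(x) {
    if (ph > 0) x <- rbind(x, x[rev(seq_len(nrow(x)))[seq_len(ph)], , drop = FALSE])
    if (pw > 0) x <- cbind(x, x[, rev(seq_len(ncol(x)))[seq_len(pw)], drop = FALSE])
    x
  }
  sbs <- lapply(arms, function(a)
    dwt_decompose(pad(a), config$wavelet, config$levels))
  fused <- mean_fuse(sbs$gauss, sbs$wiener, sbs$median)
  out <- idwt_reconstruct(fused)[seq_len(h), seq_len(w), drop = FALSE]
  clip01(out)
}

#' Enhance an image by wavelet mean-fusion of three filter arms
#'
#' Per channel: the three filter arms are decomposed with a multilevel
#' periodized db2 transform, corresponding subbands are averaged, and the
#' inverse transform reconstructs the enhanced channel (clipped to
#' \[0, 1\]). Dimensions not divisible by `2^levels` are mirror-padded for
#' the transform and cropped back.
#'
#' @param image an H x W x 3 array or a numeric matrix on \[0, 1\]
#'   (each dimension >= 8).
#' @param config an [ictef_config()].
#' @return enhanced image with the shape of the input.
#' @export
ictef_enhance <- function(image, config = ictef_config()) {
  if (is_gray_image(image)) {
    if (any(dim(image) < 8L)) stop("image must be at least 8x8")
    return(ictef_enhance_gray(image, config))
  }
  assert_rgb(image)
  if (any(dim(image)[1:2] < 8L)) stop("each channel must be at least 8x8")
  out <- image
  for (ch in 1:3) out[, , ch] <- ictef_enhance_gray(image[, , ch], config)
  out
}
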