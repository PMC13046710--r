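# Histogram of oriented gradients: [-1 0 1] gradients, magnitude-weighted
# orientation votes with bilinear bin interpolation over unsigned
# orientation [0, 180), per-cell histograms, overlapping L2-normalized
# blocks.

#' HOG configuration
#'
#' @param cell pixels per cell side (default 8).
#' @param block cells per block side (default 2).
#' @param stride cells between block origins (default 1, i.e. 50% overlap
#'   for 2-cell blocks).
#' @param bins orientation bins over \[0, 180) degrees (default 9).
#' @param eps L2 normalization guard (default 1e-6).
#' @return a list of class `hog_config`.
#' @export
hog_config <- function(cell = 8, block = 2, stride = 1, bins = 9, eps = 1e-6) {
  stopifnot(cell >= 1, block >= 1, stride >= 1, stride <= block, bins >= 1)
  structure(list(cell = as.integer(cell), block = as.integer(block),
                 stride = as.integer(stride), bins = as.integer(bins),
                 eps = eps), class = "hog_config")
}

#' Image gradients for HOG
#'
#' Central differences via the \[-1 0 1\] kernel and its transpose with
#' replicate borders; magnitude `m = sqrt(ix^2 + iy^2)` and unsigned
#' orientation `theta = atan2(iy, ix) mod 180` in degrees (0 where the
#' magnitude vanishes).
#'
#' @param image numeric matrix, at least 3x3.
#' @return a list with matrices `ix`, `iy`, `m`, `theta`.
#' @export
hog_gradients <- function(image) {
  assert_gray(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 3L || w < 3L) stop("image must be at least 3x3")
  ix <- image[, c(2:w, w)] - image[, c(1, 1:(w - 1))]
  iy <- image[c(2:h, h), ] - image[c(1, 1:(h - 1)), ]
  m <- sqrt(ix^2 + iy^2)
  theta <- atan2(iy, ix) * 180 / pi
  theta <- theta %% 180
  theta[m == 0] <- 0
  list(ix = ix, iy = iy, m = m, theta = theta)
}

#' HOG feature vector
#'
#' Per-cell orientation histograms with magnitude-weighted bilinear
#' interpolation between the two nearest bin centers (circular over 180
#' degrees), collected into overlapping blocks of `block^2` cells at cell
#' stride `stride`, each block L2-normalized and concatenated in row-major
#' block order. For the default geometry on a 256 x 256 image the vector
#' has length (32 - 1)^2 x 4 x 9 = 34,596.
#'
#' @param image numeric matrix; trailing pixels beyond a whole cell are
#'   ignored. Must contain at least one full block.
#' @param config a [hog_config()].
#' @return a numeric feature vector with attribute `"dims"` (block grid and
#'   per-block length).
#' @export
hog_features <- function(image, config = hog_config()) {
  gr <- hog_gradients(image)
  cs <- config$cell; nb <- config$bins
  ncy <- nrow(image) %/% cs; ncx <- ncol(image) %/% cs
  if (ncy < config$block || ncx < config$block)
    stop("image smaller than one block")
  ys <- seq_len(ncy * cs); xs <- seq_len(ncx * cs)
  m <- gr$m[ys, xs]; theta <- gr$theta[ys, xs]
  bw <- 180 / nb
  t <- theta / bw - 0.5
  k0 <- floor(t)
  f <- t - k0
  bin_lo <- (as.integer(k0) %% nb) + 1L
  bin_hi <- (as.integer(k0 + 1) %% nb) + 1L
  cy <- (ys - 1L) %/% cs          # 0-based cell row per pixel row
  cx <- (xs - 1L) %/% cs
  cellid <- matrix(cy, length(ys), length(xs)) +
            matrix(cx, length(ys), length(xs), byrow = TRUE) * ncy  # 0-based
  hist <- numeric(ncy * ncx * nb)
  add_votes <- function(bin, wgt) {
    idx <- as.vector(cellid) * nb + as.vector(bin)          # 1-based overall
    acc <- rowsum(as.vector(wgt), group = idx)
    hist[as.integer(rownames(acc))] <<- hist[as.integer(rownames(acc))] + acc[, 1]
  }
  add_votes(bin_lo, (1 - f) * m)
  add_votes(bin_hi, f * m)
  ch <- array(hist, c(nb, ncy, ncx))
  bsz <- config$block; st <- config$stride
  bys <- seq(1L, ncy - bsz + 1L, by = st)
  bxs <- seq(1L, ncx - bsz + 1L, by = st)
  blen <- bsz * bsz * nb
  out <- numeric(length(bys) * length(bxs) * blen)
  pos <- 0L
  for (by in bys) for (bx in bxs) {
    v <- as.vector(ch[, by:(by + bsz - 1L), bx:(bx + bsz - 1L)])
    out[pos + seq_len(blen)] <- v / sqrt(sum(v^2) + config$eps^2)
    pos <- pos + blen
  }
  attr(out, "dims") <- c(blocks_y = length(bys), blocks_x = length(bxs),
                         block_length = blen)
  out
}
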