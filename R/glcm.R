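# Gray-level co-occurrence matrix and its six texture statistics.

#' Gray-level co-occurrence matrix
#'
#' Quantizes intensities uniformly on \[0, 1\] to `levels` gray levels,
#' counts ordered pixel pairs at the given displacement, optionally
#' symmetrizes (adds the transpose), and normalizes to probabilities.
#'
#' @param image numeric matrix on \[0, 1\].
#' @param levels number of gray levels N (default 8).
#' @param distance pair displacement in pixels (default 1).
#' @param angle one of 0, 45, 90, 135 degrees (default 0, horizontal).
#' @param symmetric count each pair in both directions (default `TRUE`).
#' @return an object of class `glcm_matrix`: list with `P` (N x N
#'   probability matrix, rows/cols indexed by gray level 0..N-1), `levels`,
#'   `distance`, `angle`, `symmetric`.
#' @export
compute_glcm <- function(image, levels = 8, distance = 1, angle = 0,
                         symmetric = TRUE) {
  assert_gray(image)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (!angle %in% c(0, 45, 90, 135)) stop("angle must be one of 0, 45, 90, 135")
  d <- as.integer(distance)
  off <- switch(as.character(angle),
                "0"   = c(0L, d),
                "45"  = c(-d, d),
                "90"  = c(-d, 0L),
                "135" = c(-d, -d))
  h <- nrow(image); w <- ncol(image)
  if (h <= abs(off[1]) || w <= abs(off[2]))
    stop("image smaller than the offset span")
  q <- pmin(floor(clip01(image) * levels), levels - 1L)
  ys <- seq_len(h - abs(off[1])); xs <- seq_len(w - abs(off[2]))
  y0 <- ys + max(0L, -off[1]); x0 <- xs + max(0L, -off[2])
  y1 <- y0 + off[1]; x1 <- x0 + off[2]
  i <- q[y0, x0]; j <- q[y1, x1]
  counts <- matrix(tabulate(i * levels + j + 1L, levels^2), levels, levels,
                   byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(P = counts / sum(counts), levels = levels,
                 distance = d, angle = angle, symmetric = symmetric),
            class = "glcm_matrix")
}

#' Texture statistics of a co-occurrence matrix
#'
#' Computes contrast, correlation, energy, homogeneity, autocorrelation,
#' and entropy of a normalized co-occurrence matrix, with gray levels
#' indexed 0..N-1:
#' \deqn{CT = \sum_{ij} (i-j)^2 P_{ij}, \quad EN = \sum_{ij} P_{ij}^2, \quad
#'       HM = \sum_{ij} P_{ij} / (1 + |i-j|),}
#' \deqn{AC = \sum_{ij} i j P_{ij}, \quad ET = -\sum_{ij} P_{ij} \ln P_{ij},}
#' and correlation \eqn{CR = \sum_{ij} (i-\mu_i)(j-\mu_j) P_{ij} /
#' (\sigma_i \sigma_j)} using the row/column marginal standard deviations,
#' which keeps CR in \[-1, 1\]. Zero entries contribute nothing to the
#' entropy. A degenerate matrix with zero marginal variance (a constant
#' image) reports CR = 1 with a warning: a constant field is perfectly
#' self-similar.
#'
#' @param glcm a `glcm_matrix`, or a raw N x N probability matrix.
#' @return a named numeric vector with elements `contrast`, `correlation`,
#'   `energy`, `homogeneity`, `autocorrelation`, `entropy`.
#' @export
glcm_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm_matrix")) glcm$P else glcm
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("co-occurrence matrix must sum to 1")
  n <- nrow(P)
  lev <- 0:(n - 1)
  I <- matrix(lev, n, n); J <- matrix(lev, n, n, byrow = TRUE)
  pi_ <- rowSums(P); pj <- colSums(P)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
  s_i <- sqrt(sum((lev - mu_i)^2 * pi_)); s_j <- sqrt(sum((lev - mu_j)^2 * pj))
  if (s_i == 0 || s_j == 0) {
    warning("degenerate co-occurrence matrix (zero marginal variance); correlation set to 1")
    corr <- 1
  } else {
    corr <- sum((I - mu_i) * (J - mu_j) * P) / (s_i * s_j)
  }
  ent_terms <- ifelse(P > 0, -P * log(P), 0)
  c(contrast = sum((I - J)^2 * P),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(I - J))),
    autocorrelation = sum(I * J * P),
    entropy = sum(ent_terms))
}
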