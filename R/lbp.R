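# Local binary patterns: the conventional 8-neighbor code and the
# four-directional variant (top/bottom/left/right 3-neighbor codes).

# The eight 3x3 neighbors of every interior pixel, row-major:
#   p1 p2 p3 / p4 c p5 / p6 p7 p8
neighbor_planes <- function(image) {
  h <- nrow(image); w <- ncol(image)
  if (h < 3L || w < 3L) stop("image must be at least 3x3")
  list(
    c  = image[2:(h - 1), 2:(w - 1), drop = FALSE],
    p1 = image[1:(h - 2), 1:(w - 2), drop = FALSE],
    p2 = image[1:(h - 2), 2:(w - 1), drop = FALSE],
    p3 = image[1:(h - 2), 3:w,       drop = FALSE],
    p4 = image[2:(h - 1), 1:(w - 2), drop = FALSE],
    p5 = image[2:(h - 1), 3:w,       drop = FALSE],
    p6 = image[3:h,       1:(w - 2), drop = FALSE],
    p7 = image[3:h,       2:(w - 1), drop = FALSE],
    p8 = image[3:h,       3:w,       drop = FALSE])
}

#' Conventional local binary pattern map
#'
#' For every interior pixel, the eight neighbors are compared strictly
#' against the center (ties give bit 0) and packed into one byte with p1 as
#' the most significant bit and p8 as the least.
#'
#' @param image numeric matrix, at least 3x3.
#' @return an integer matrix of codes in 0..255 over interior pixels
#'   (size (H-2) x (W-2)).
#' @export
lbp_map <- function(image) {
  assert_gray(image)
  n <- neighbor_planes(image)
  codes <- 128L * (n$p1 > n$c) + 64L * (n$p2 > n$c) + 32L * (n$p3 > n$c) +
           16L * (n$p4 > n$c) + 8L * (n$p5 > n$c) + 4L * (n$p6 > n$c) +
           2L * (n$p7 > n$c) + 1L * (n$p8 > n$c)
  storage.mode(codes) <- "integer"
  codes
}

#' Conventional LBP histogram
#'
#' @param image numeric matrix, at least 3x3.
#' @param normalize divide by the interior pixel count (default `FALSE`,
#'   raw counts).
#' @return a 256-bin count vector over codes 0..255.
#' @export
lbp_histogram <- function(image, normalize = FALSE) {
  codes <- lbp_map(image)
  h <- tabulate(as.vector(codes) + 1L, 256L)
  if (normalize) h <- h / length(codes)
  h
}

#' Four-directional local binary pattern maps
#'
#' Splits the 3x3 window into top (p1, p2, p3), bottom (p6, p7, p8), left
#' (p1, p4, p6), and right (p3, p5, p8) neighbor triples, thresholds each
#' strictly against the center, and packs 3-bit codes with the first listed
#' neighbor as the most significant bit.
#'
#' @param image numeric matrix, at least 3x3.
#' @return an object of class `ilbp_maps`: list of integer matrices `U`,
#'   `B`, `L`, `R` with codes in 0..7 over interior pixels.
#' @export
ilbp_maps <- function(image) {
  assert_gray(image)
  n <- neighbor_planes(image)
  pack3 <- function(a, b, c) {
    m <- 4L * (a > n$c) + 2L * (b > n$c) + 1L * (c > n$c)
    storage.mode(m) <- "integer"
    m
  }
  structure(list(U = pack3(n$p1, n$p2, n$p3),
                 B = pack3(n$p6, n$p7, n$p8),
                 L = pack3(n$p1, n$p4, n$p6),
                 R = pack3(n$p3, n$p5, n$p8)),
            class = "ilbp_maps")
}

#' Four-directional LBP feature vector
#'
#' Concatenates the four 8-bin raw-count histograms (order U, B, L, R) of
#' the directional code maps into a 32-value texture descriptor. Each
#' histogram sums to the interior pixel count.
#'
#' @param image numeric matrix, at least 3x3.
#' @param normalize divide histograms by the interior pixel count
#'   (default `FALSE`).
#' @return a named numeric vector of length 32.
#' @export
ilbp_features <- function(image, normalize = FALSE) {
  maps <- ilbp_maps(image)
  hists <- lapply(unclass(maps)[c("U", "B", "L", "R")], function(m)
    tabulate(as.vector(m) + 1L, 8L))
  out <- unlist(hists, use.names = FALSE)
  if (normalize) out <- out / length(maps$U)
  names(out) <- paste0(rep(c("U", "B", "L", "R"), each = 8L), rep(0:7, 4L))
  out
}
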