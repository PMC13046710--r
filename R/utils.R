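#' @importFrom stats rnorm runif sd median fft approx predict
#' @importFrom utils head tail write.csv
#' @importFrom graphics plot
NULL

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

is_rgb_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

assert_gray <- function(x) {
  if (!is_gray_image(x)) stop("expected a numeric matrix (grayscale image)")
  if (any(!is.finite(x))) stop("image contains non-finite values")
  invisible(x)
}

assert_rgb <- function(x) {
  if (!is_rgb_image(x)) stop("expected an H x W x 3 numeric array (RGB image)")
  if (any(!is.finite(x))) stop("image contains non-finite values")
  invisible(x)
}

#' Convert an RGB image to grayscale
#'
#' Applies the conventional luma weights 0.299/0.587/0.114 to an H x W x 3
#' array on \[0, 1\]. Grayscale input is returned unchanged.
#'
#' @param img an H x W x 3 numeric array, or a numeric matrix.
#' @return a numeric matrix on the same intensity scale.
#' @export
rgb_to_gray <- function(img) {
  if (is_gray_image(img)) return(img)
  assert_rgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Evaluate f under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so library calls never perturb user code.
with_seed <- function(seed, f) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}

# Bilinear resize of a matrix or RGB array via EBImage.
resize_image <- function(img, h, w) {
  if (is_gray_image(img)) {
    out <- EBImage::imageData(EBImage::resize(EBImage::Image(img), w = h, h = w))
    return(matrix(out, h, w))
  }
  assert_rgb(img)
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- matrix(
    EBImage::imageData(EBImage::resize(EBImage::Image(img[, , ch]), w = h, h = w)), h, w)
  out
}

#' Read an image file
#'
#' Reads a PNG (via the png package) or other raster format (via EBImage)
#' into an H x W x 3 array on \[0, 1\]. Grayscale files are replicated across
#' channels.
#'
#' @param path file path.
#' @return an H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    x <- EBImage::imageData(img)
    if (length(dim(x)) == 3L) x <- aperm(x, c(2, 1, 3)) else x <- t(x)
  }
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3))
  if (length(dim(x)) == 3L && dim(x)[3] > 3L) x <- x[, , 1:3]
  x
}

#' Write an image as 8-bit PNG
#'
#' @param img a numeric matrix or H x W x 3 array on \[0, 1\].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clip01(img), path)
  invisible(path)
}
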