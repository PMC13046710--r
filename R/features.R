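# Handcrafted feature extraction: [GLCM (6) | ILBP (32) | HOG] per image.

#' Feature extraction configuration
#'
#' @param glcm,ilbp,hog logical toggles for the three descriptor families.
#' @param glcm_levels,glcm_distance,glcm_angle co-occurrence parameters.
#' @param hog_config a [hog_config()].
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(glcm = TRUE, ilbp = TRUE, hog = TRUE,
                           glcm_levels = 8, glcm_distance = 1, glcm_angle = 0,
                           hog_config = dermatex::hog_config()) {
  if (!glcm && !ilbp && !hog) stop("at least one feature family must be enabled")
  structure(list(glcm = glcm, ilbp = ilbp, hog = hog,
                 glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                 glcm_angle = glcm_angle, hog_config = hog_config),
            class = "feature_config")
}

#' Extract the handcrafted feature vector of one image
#'
#' Converts to grayscale (luma weights) and concatenates, in fixed order,
#' the six co-occurrence statistics, the 32-value four-directional LBP
#' histogram, and the HOG vector. With defaults on a 256 x 256 image the
#' vector has length 6 + 32 + 34,596 = 34,634.
#'
#' @param image an RGB array or grayscale matrix on \[0, 1\].
#' @param config a [feature_config()].
#' @return a numeric vector with attribute `"segments"` giving the length
#'   of each enabled segment.
#' @export
extract_features <- function(image, config = feature_config()) {
  gray <- rgb_to_gray(image)
  parts <- list(); segs <- integer(0)
  if (config$glcm) {
    g <- glcm_features(compute_glcm(gray, levels = config$glcm_levels,
                                    distance = config$glcm_distance,
                                    angle = config$glcm_angle))
    parts <- c(parts, list(unname(g))); segs <- c(segs, glcm = length(g))
  }
  if (config$ilbp) {
    v <- unname(ilbp_features(gray))
    parts <- c(parts, list(v)); segs <- c(segs, ilbp = length(v))
  }
  if (config$hog) {
    v <- as.numeric(hog_features(gray, config$hog_config))
    parts <- c(parts, list(v)); segs <- c(segs, hog = length(v))
  }
  out <- unlist(parts, use.names = FALSE)
  attr(out, "segments") <- segs
  out
}

#' Extract features for a batch of images
#'
#' @param images an H x W x 3 x N array (or H x W x N for grayscale).
#' @param config a [feature_config()].
#' @return an N x L numeric matrix with attributes `"segments"` and
#'   `"config"` (the configuration used, kept for alignment checks when
#'   training).
#' @export
extract_feature_matrix <- function(images, config = feature_config()) {
  nd <- length(dim(images))
  n <- dim(images)[nd]
  get_img <- function(i) if (nd == 4L) images[, , , i] else images[, , i]
  f1 <- extract_features(get_img(1), config)
  out <- matrix(0, n, length(f1))
  out[1, ] <- f1
  if (n > 1) for (i in 2:n) out[i, ] <- extract_features(get_img(i), config)
  attr(out, "segments") <- attr(f1, "segments")
  attr(out, "config") <- config
  out
}
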