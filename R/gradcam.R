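# Gradient-weighted class activation mapping on the 2D branch.

#' Grad-CAM heatmap for one image
#'
#' Computes the gradient of the target-class logit with respect to the
#' post-ReLU activation of the last 2D convolutional block, averages it
#' spatially into per-channel weights, forms the ReLU of the weighted
#' activation sum, upsamples it bilinearly to the input resolution, and
#' max-normalizes to \[0, 1\] when nonzero.
#'
#' @param object a fitted `sdnet` whose configuration includes the 2D
#'   branch.
#' @param image one H x W x 3 array.
#' @param features optional feature vector (needed when the 1D branch is
#'   active); standardization from the fit is applied.
#' @param target_class class label or index to explain; defaults to the
#'   predicted class.
#' @return an object of class `grad_cam`: list with `raw` (conv-grid map),
#'   `upsampled` (input-resolution map in \[0, 1\]), `target_class`,
#'   `weights` (per-channel pooled gradients).
#' @export
grad_cam <- function(object, image, features = NULL, target_class = NULL) {
  stopifnot(inherits(object, "sdnet"))
  config <- object$config
  if (!"2d" %in% config$branches) stop("Grad-CAM needs the 2D branch")
  assert_rgb(image)
  images <- array(image, c(dim(image), 1L))
  if (!is.null(features)) {
    features <- matrix(as.numeric(features), 1L)
    if (!is.null(object$scaling))
      features <- sweep(sweep(features, 2L, object$scaling$center),
                        2L, object$scaling$scale, `/`)
  } else if ("1d" %in% config$branches) {
    stop("model uses the 1D branch; supply its feature vector")
  }
  fw <- sdnet_forward(object$params, object$buffers, config, images, features,
                      training = FALSE, keep_cache = TRUE)
  k <- config$num_classes
  if (is.null(target_class)) {
    tc <- which.max(fw$probs[1, ])
  } else if (is.character(target_class)) {
    tc <- match(target_class, object$classes)
    if (is.na(tc)) stop("unknown class: ", target_class)
  } else {
    tc <- as.integer(target_class)
    if (tc < 1L || tc > k) stop("target class index out of range")
  }
  dlogits <- matrix(0, 1L, k)
  dlogits[1L, tc] <- 1
  bw <- sdnet_backward(object$params, config, fw, dlogits, relu_grad_of = 3L)
  cc <- fw$fwd2$caches[[3]]
  hc <- cc$h; wc <- cc$w; nch <- ncol(cc$relu_out)
  act <- array(cc$relu_out, c(hc, wc, nch))
  grad <- array(bw$relu_grad_2d, c(hc, wc, nch))
  wts <- apply(grad, 3L, mean)
  cam <- matrix(0, hc, wc)
  for (ch in seq_len(nch)) cam <- cam + wts[ch] * act[, , ch]
  cam <- pmax(cam, 0)
  up <- resize_image(cam, dim(image)[1], dim(image)[2])
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  raw <- cam
  if (max(raw) > 0) raw <- raw / max(raw)
  structure(list(raw = raw, upsampled = up,
                 target_class = object$classes[tc], weights = wts),
            class = "grad_cam")
}

#' @export
print.grad_cam <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap for class '%s': %d x %d conv grid -> %d x %d\n",
              x$target_class, nrow(x$raw), ncol(x$raw),
              nrow(x$upsampled), ncol(x$upsampled)))
  invisible(x)
}

#' Save a Grad-CAM overlay as PNG
#'
#' Blends the heatmap (red channel) onto the grayscale image.
#'
#' @param cam a `grad_cam`.
#' @param image the image that was explained.
#' @param path output PNG path.
#' @param alpha heatmap opacity.
#' @return the path, invisibly.
#' @export
write_gradcam_overlay <- function(cam, image, path, alpha = 0.5) {
  gray <- rgb_to_gray(image)
  hm <- cam$upsampled
  out <- array(0, c(dim(gray), 3))
  out[, , 1] <- clip01(gray * (1 - alpha) + hm * alpha)
  out[, , 2] <- clip01(gray * (1 - alpha))
  out[, , 3] <- clip01(gray * (1 - alpha) + (1 - hm) * alpha * 0.3)
  write_image(out, path)
}
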