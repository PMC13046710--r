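# Dual-branch classifier: a 2D convolutional branch on RGB images and a 1D
# convolutional branch on the handcrafted feature vector, concatenated into
# a fully connected softmax head. Each branch stacks three blocks of
# Conv -> ReLU -> BatchNorm -> MaxPool(stride 2).

#' Dual-branch network configuration
#'
#' @param num_classes number of output classes (default 5).
#' @param image_size `c(height, width)` of the 2D-branch input (default
#'   256 x 256; any size >= 8 works, spatial dims are halved three times).
#' @param channels image channels (default 3).
#' @param vector_length length of the 1D-branch input (default 34,634, the
#'   full GLCM + ILBP + HOG concatenation at 256 x 256).
#' @param conv2d_filters,conv1d_filters filters of the three blocks of each
#'   branch (default `c(64, 128, 256)`).
#' @param fc_bias include a bias in the fully connected head (default
#'   `TRUE`).
#' @param branches character vector, subset of `c("2d", "1d")`; dropping a
#'   branch gives the single-branch ablation models.
#' @return a list of class `sdnet_config`.
#' @export
sdnet_config <- function(num_classes = 5, image_size = c(256, 256),
                         channels = 3, vector_length = 34634,
                         conv2d_filters = c(64, 128, 256),
                         conv1d_filters = c(64, 128, 256),
                         fc_bias = TRUE, branches = c("2d", "1d")) {
  stopifnot(num_classes >= 2, all(conv2d_filters > 0), all(conv1d_filters > 0),
            length(conv2d_filters) == 3L, length(conv1d_filters) == 3L,
            length(branches) >= 1L, all(branches %in% c("2d", "1d")))
  if ("2d" %in% branches && any(image_size < 8)) stop("image_size must be >= 8")
  if ("1d" %in% branches && vector_length < 8) stop("vector_length must be >= 8")
  structure(list(num_classes = as.integer(num_classes),
                 image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 vector_length = as.integer(vector_length),
                 conv2d_filters = as.integer(conv2d_filters),
                 conv1d_filters = as.integer(conv1d_filters),
                 fc_bias = isTRUE(fc_bias), branches = branches),
            class = "sdnet_config")
}

#' Architecture-table compatibility configuration
#'
#' The configuration whose printed layer table the package reproduces
#' exactly: 256 x 256 x 3 images, a 34,596-long 1D input (HOG alone), four
#' output units, and a biasless fully connected head.
#'
#' @return an `sdnet_config`.
#' @export
table2_config <- function() {
  sdnet_config(num_classes = 4, vector_length = 34596, fc_bias = FALSE)
}

#' Layer shapes and trainable-parameter accounting
#'
#' Walks the architecture for a configuration and returns one row per
#' sublayer with its output shape and trainable parameter count (Conv2D:
#' `3*3*Cin*Cout + Cout`; Conv1D: `3*Cin*Cout + Cout`; BatchNorm: `2*C`;
#' FC: `D*K` plus `K` if biased). For [table2_config()] the flatten lengths
#' are 262,144 (2D) and 1,106,944 (1D), the concatenation 1,369,088, and
#' the head 5,476,352.
#'
#' @param config an [sdnet_config()].
#' @return a data.frame with columns `model`, `sublayer`, `output`,
#'   `params`.
#' @export
sdnet_param_table <- function(config = sdnet_config()) {
  stopifnot(inherits(config, "sdnet_config"))
  rows <- list()
  add <- function(model, sublayer, output, params)
    rows[[length(rows) + 1L]] <<- data.frame(model = model, sublayer = sublayer,
                                             output = output, params = params)
  flat <- c()
  if ("2d" %in% config$branches) {
    h <- config$image_size[1]; w <- config$image_size[2]; cin <- config$channels
    add("2D-CNN", "Input", sprintf("%d x %d x %d", h, w, cin), 0)
    for (i in 1:3) {
      cout <- config$conv2d_filters[i]
      add("2D-CNN", sprintf("Conv2D_%d", i), sprintf("%d x %d x %d", h, w, cout),
          9L * cin * cout + cout)
      add("2D-CNN", sprintf("ReLU_%d", i), sprintf("%d x %d x %d", h, w, cout), 0)
      add("2D-CNN", sprintf("BatchNorm_%d", i), sprintf("%d x %d x %d", h, w, cout),
          2L * cout)
      h <- h %/% 2L; w <- w %/% 2L
      add("2D-CNN", sprintf("MaxPool_%d", i), sprintf("%d x %d x %d", h, w, cout), 0)
      cin <- cout
    }
    f2 <- h * w * cin
    add("2D-CNN", "Flatten", as.character(f2), 0)
    flat <- c(flat, `2d` = f2)
  }
  if ("1d" %in% config$branches) {
    l <- config$vector_length; cin <- 1L
    add("1D-CNN", "Input", sprintf("%d x 1", l), 0)
    for (i in 1:3) {
      cout <- config$conv1d_filters[i]
      add("1D-CNN", sprintf("Conv1D_%d", i), sprintf("%d x %d", l, cout),
          3L * cin * cout + cout)
      add("1D-CNN", sprintf("ReLU_%d", i), sprintf("%d x %d", l, cout), 0)
      add("1D-CNN", sprintf("BatchNorm_%d", i), sprintf("%d x %d", l, cout),
          2L * cout)
      l <- l %/% 2L
      add("1D-CNN", sprintf("MaxPool_%d", i), sprintf("%d x %d", l, cout), 0)
      cin <- cout
    }
    f1 <- l * cin
    add("1D-CNN", "Flatten", as.character(f1), 0)
    flat <- c(flat, `1d` = f1)
  }
  d <- sum(flat)
  add("Fusion", "Concatenation", as.character(d), 0)
  add("FC", "FullyConnected", as.character(config$num_classes),
      d * config$num_classes + if (config$fc_bias) config$num_classes else 0L)
  add("Classifier", "Softmax", as.character(config$num_classes), 0)
  out <- do.call(rbind, rows)
  attr(out, "flatten") <- flat
  attr(out, "total") <- sum(out$params)
  out
}

#' Count trainable parameters
#'
#' @param x an `sdnet_config` or fitted `sdnet` object.
#' @return total trainable parameter count.
#' @export
count_parameters <- function(x) {
  config <- if (inherits(x, "sdnet")) x$config else x
  attr(sdnet_param_table(config), "total")
}

# ---- initialization -------------------------------------------------------

sdnet_init <- function(config, seed = 1) {
  tab <- sdnet_param_table(config)
  flat <- attr(tab, "flatten")
  with_seed(seed, function() {
    params <- list(); buffers <- list()
    init_branch <- function(prefix, taps, cin0, filters) {
      cin <- cin0
      for (i in 1:3) {
        cout <- filters[i]
        params[[paste0(prefix, i, ".W")]] <<-
          array(rnorm(taps * cin * cout, 0, sqrt(2 / (taps * cin))),
                c(taps, cin, cout))
        params[[paste0(prefix, i, ".b")]] <<- numeric(cout)
        params[[paste0(prefix, "bn", i, ".gamma")]] <<- rep(1, cout)
        params[[paste0(prefix, "bn", i, ".beta")]] <<- numeric(cout)
        buffers[[paste0(prefix, "bn", i, ".rm")]] <<- numeric(cout)
        buffers[[paste0(prefix, "bn", i, ".rv")]] <<- rep(1, cout)
        cin <- cout
      }
    }
    if ("2d" %in% config$branches)
      init_branch("c2d", 9L, config$channels, config$conv2d_filters)
    if ("1d" %in% config$branches)
      init_branch("c1d", 3L, 1L, config$conv1d_filters)
    d <- sum(flat)
    # small-scale head initialization: initial logits near zero, so a fresh
    # model predicts close to the uniform distribution
    params[["fc.W"]] <- matrix(rnorm(d * config$num_classes, 0, 0.01),
                               d, config$num_classes)
    if (config$fc_bias) params[["fc.b"]] <- numeric(config$num_classes)
    list(params = params, buffers = buffers, flatten = flat)
  })
}

# ---- forward / backward ---------------------------------------------------

branch_forward <- function(x, h, w, b, prefix, kind, params, buffers,
                           filters, training) {
  offsets <- conv_offsets(kind)
  caches <- list()
  for (i in 1:3) {
    Wk <- params[[paste0(prefix, i, ".W")]]
    conv_in <- x
    x <- conv_forward(x, Wk, params[[paste0(prefix, i, ".b")]], h, w, b, offsets)
    relu_mask <- x > 0
    x <- x * relu_mask
    relu_out <- x
    bn <- bn_forward(x, params[[paste0(prefix, "bn", i, ".gamma")]],
                     params[[paste0(prefix, "bn", i, ".beta")]],
                     buffers[[paste0(prefix, "bn", i, ".rm")]],
                     buffers[[paste0(prefix, "bn", i, ".rv")]], training)
    if (training) {
      buffers[[paste0(prefix, "bn", i, ".rm")]] <- bn$rm
      buffers[[paste0(prefix, "bn", i, ".rv")]] <- bn$rv
    }
    pool <- maxpool_forward(bn$out, h, w, b)
    caches[[i]] <- list(conv_in = conv_in, relu_mask = relu_mask,
                        relu_out = relu_out, bn = bn, pool = pool,
                        bn_in = bn$out, h = h, w = w)
    x <- pool$out
    h <- h %/% 2L; w <- max(w %/% 2L, 1L)
  }
  list(out = x, h = h, w = w, caches = caches, buffers = buffers)
}

branch_backward <- function(dout, fwd, b, prefix, kind, params,
                            relu_grad_of = 0L) {
  offsets <- conv_offsets(kind)
  grads <- list()
  relu_grad <- NULL
  for (i in 3:1) {
    cc <- fwd$caches[[i]]
    dout <- maxpool_backward(cc$pool, dout, cc$bn_in, cc$h, cc$w, b)
    bnb <- bn_backward(cc$bn, dout, params[[paste0(prefix, "bn", i, ".gamma")]])
    grads[[paste0(prefix, "bn", i, ".gamma")]] <- bnb$dgamma
    grads[[paste0(prefix, "bn", i, ".beta")]] <- bnb$dbeta
    dout <- bnb$dx
    if (i == relu_grad_of) relu_grad <- dout       # d loss / d relu_i output
    dout <- dout * cc$relu_mask
    cb <- conv_backward(cc$conv_in, dout, params[[paste0(prefix, i, ".W")]],
                        cc$h, cc$w, b, offsets)
    grads[[paste0(prefix, i, ".W")]] <- cb$dW
    grads[[paste0(prefix, i, ".b")]] <- cb$db
    dout <- cb$dx
  }
  list(grads = grads, dx = dout, relu_grad = relu_grad)
}

# images: H x W x C x B array; features: B x L matrix.
sdnet_forward <- function(params, buffers, config, images = NULL,
                          features = NULL, training = FALSE,
                          keep_cache = FALSE) {
  use2d <- "2d" %in% config$branches
  use1d <- "1d" %in% config$branches
  b <- if (use2d) dim(images)[4] else nrow(features)
  parts <- list(); fwd2 <- fwd1 <- NULL
  if (use2d) {
    h <- dim(images)[1]; w <- dim(images)[2]
    x2 <- matrix(aperm(images, c(1, 2, 4, 3)), h * w * b, dim(images)[3])
    fwd2 <- branch_forward(x2, h, w, b, "c2d", "2d", params, buffers,
                           config$conv2d_filters, training)
    buffers <- fwd2$buffers
    parts <- c(parts, list(flatten_batch(fwd2$out, fwd2$h * fwd2$w, b)))
  }
  if (use1d) {
    l <- ncol(features)
    x1 <- matrix(as.vector(t(features)), l * b, 1L)
    fwd1 <- branch_forward(x1, l, 1L, b, "c1d", "1d", params, buffers,
                           config$conv1d_filters, training)
    buffers <- fwd1$buffers
    parts <- c(parts, list(flatten_batch(fwd1$out, fwd1$h, b)))
  }
  z <- do.call(cbind, parts)
  logits <- z %*% params[["fc.W"]]
  if (!is.null(params[["fc.b"]]))
    logits <- sweep(logits, 2L, params[["fc.b"]], `+`)
  probs <- softmax_rows(logits)
  out <- list(logits = logits, probs = probs, buffers = buffers, b = b)
  if (keep_cache) out <- c(out, list(z = z, fwd2 = fwd2, fwd1 = fwd1,
                                     split = vapply(parts, ncol, 1L)))
  out
}

sdnet_backward <- function(params, config, fw, dlogits, relu_grad_of = 0L) {
  grads <- list()
  grads[["fc.W"]] <- crossprod(fw$z, dlogits)
  if (!is.null(params[["fc.b"]])) grads[["fc.b"]] <- colSums(dlogits)
  dz <- dlogits %*% t(params[["fc.W"]])
  pos <- 0L; relu_grad <- NULL
  if (!is.null(fw$fwd2)) {
    d2 <- dz[, pos + seq_len(fw$split[1]), drop = FALSE]
    pos <- pos + fw$split[1]
    hw <- fw$fwd2$h * fw$fwd2$w
    dmat <- unflatten_batch(d2, hw, fw$b, ncol(fw$fwd2$out))
    bb <- branch_backward(dmat, fw$fwd2, fw$b, "c2d", "2d", params,
                          relu_grad_of)
    grads <- c(grads, bb$grads)
    relu_grad <- bb$relu_grad
  }
  if (!is.null(fw$fwd1)) {
    d1 <- dz[, pos + seq_len(fw$split[length(fw$split)]), drop = FALSE]
    dmat <- unflatten_batch(d1, fw$fwd1$h, fw$b, ncol(fw$fwd1$out))
    bb <- branch_backward(dmat, fw$fwd1, fw$b, "c1d", "1d", params)
    grads <- c(grads, bb$grads)
  }
  list(grads = grads, relu_grad_2d = relu_grad)
}

# ---- fitting --------------------------------------------------------------

#' Fit the dual-branch skin-disease classifier
#'
#' Trains the two-branch convolutional network with Adam on cross-entropy
#' loss. Handcrafted features are standardized (per-dimension z-score,
#' fitted on the training samples only) before entering the 1D branch,
#' since raw co-occurrence statistics, pattern counts, and gradient
#' histograms live on very different scales. The learning rate is
#' multiplied by `decay_rate` every `decay_every` epochs.
#'
#' @param images H x W x 3 x N array on \[0, 1\], or `NULL` for the
#'   1D-only ablation.
#' @param features N x L numeric matrix, or `NULL` for the 2D-only
#'   ablation.
#' @param labels factor (or vector coercible to one) of length N.
#' @param config an [sdnet_config()]; defaults to one matching the inputs.
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param lr initial Adam learning rate (default 0.001).
#' @param decay_rate,decay_every step learning-rate schedule (default 0.5
#'   every 50 epochs).
#' @param split optional stratified train/test fraction (e.g. 0.7 trains on
#'   70% and reports held-out accuracy); `NULL` trains on all samples.
#' @param standardize z-score the feature matrix (default `TRUE`).
#' @param seed seed controlling initialization, the split, and batch
#'   shuffling; fixed seed gives a reproducible loss history.
#' @param verbose print per-epoch progress.
#' @return an object of class `sdnet` with elements `params`, `buffers`,
#'   `config`, `classes`, `history` (per-epoch data.frame), `scaling`,
#'   `test` (held-out indices, predictions and accuracy when `split` is
#'   used).
#' @export
sdnet <- function(images = NULL, features = NULL, labels,
                  config = NULL, epochs = 30, batch_size = 32, lr = 0.001,
                  decay_rate = 0.5, decay_every = 50, split = NULL,
                  standardize = TRUE, seed = 1, verbose = FALSE) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("labels must contain at least two classes")
  n <- length(labels)
  if (!is.null(images) && dim(images)[4] != n)
    stop("images and labels disagree in sample count")
  if (!is.null(features) && nrow(features) != n)
    stop("features and labels disagree in sample count")
  feature_config <- attr(features, "config")
  if (is.null(config)) {
    branches <- c(if (!is.null(images)) "2d", if (!is.null(features)) "1d")
    config <- sdnet_config(num_classes = nlevels(labels),
                           image_size = if (!is.null(images)) dim(images)[1:2] else c(256L, 256L),
                           vector_length = if (!is.null(features)) ncol(features) else 34634L,
                           branches = branches)
  }
  if (config$num_classes != nlevels(labels))
    stop("config num_classes does not match the labels")
  if ("2d" %in% config$branches && is.null(images)) stop("2d branch needs images")
  if ("1d" %in% config$branches && is.null(features)) stop("1d branch needs features")

  train_idx <- seq_len(n); test_idx <- integer(0)
  if (!is.null(split)) {
    stopifnot(split > 0, split < 1)
    train_idx <- with_seed(seed + 1L, function() stratified_split(labels, split))
    test_idx <- setdiff(seq_len(n), train_idx)
  }
  y <- as.integer(labels)
  scaling <- NULL
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (standardize) {
      ctr <- colMeans(features[train_idx, , drop = FALSE])
      scl <- apply(features[train_idx, , drop = FALSE], 2L, sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      features <- sweep(sweep(features, 2L, ctr), 2L, scl, `/`)
      scaling <- list(center = ctr, scale = scl)
    }
  }
  init <- sdnet_init(config, seed)
  params <- init$params; buffers <- init$buffers
  state <- adam_init(params)
  k <- config$num_classes
  hist_rows <- vector("list", epochs)
  with_seed(seed + 2L, function() {
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * decay_rate^((ep - 1L) %/% decay_every)
      ord <- sample(train_idx)
      nb <- ceiling(length(ord) / batch_size)
      loss_sum <- 0; correct <- 0L
      for (bi in seq_len(nb)) {
        ids <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(ord))]
        bimg <- if (!is.null(images) && "2d" %in% config$branches)
          images[, , , ids, drop = FALSE] else NULL
        bfeat <- if (!is.null(features) && "1d" %in% config$branches)
          features[ids, , drop = FALSE] else NULL
        fw <- sdnet_forward(params, buffers, config, bimg, bfeat,
                            training = TRUE, keep_cache = TRUE)
        buffers <<- fw$buffers
        onehot <- matrix(0, length(ids), k)
        onehot[cbind(seq_along(ids), y[ids])] <- 1
        p <- pmax(fw$probs, 1e-12)
        loss_sum <- loss_sum + -mean(log(p[cbind(seq_along(ids), y[ids])])) * length(ids)
        correct <- correct + sum(max.col(fw$probs, ties.method = "first") == y[ids])
        dlogits <- (fw$probs - onehot) / length(ids)
        bw <- sdnet_backward(params, config, fw, dlogits)
        upd <- adam_step(params, bw$grads, state, lr_ep)
        params <<- upd$params; state <<- upd$state
      }
      hist_rows[[ep]] <<- data.frame(epoch = ep,
                                     loss = loss_sum / length(ord),
                                     accuracy = correct / length(ord),
                                     lr = lr_ep)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        loss_sum / length(ord), correct / length(ord)))
    }
  })
  fit <- structure(list(params = params, buffers = buffers, config = config,
                        classes = levels(labels),
                        history = do.call(rbind, hist_rows),
                        scaling = scaling, feature_config = feature_config,
                        seed = seed, test = NULL),
                   class = "sdnet")
  if (length(test_idx) > 0) {
    pr <- predict(fit,
                  images = if (!is.null(images)) images[, , , test_idx, drop = FALSE],
                  features = if (!is.null(features)) features[test_idx, , drop = FALSE],
                  type = "class", .prescaled = TRUE)
    fit$test <- list(indices = test_idx, predicted = pr,
                     truth = labels[test_idx],
                     accuracy = mean(pr == labels[test_idx]))
  }
  fit
}

# Stratified sample of round(frac * n_k) indices per class (at least 1).
stratified_split <- function(labels, frac) {
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    m <- max(1L, round(frac * length(ix)))
    if (length(ix) == 1L) ix else sample(ix, m)
  }), use.names = FALSE)
}

#' Predict classes or probabilities from a fitted network
#'
#' @param object a fitted `sdnet`.
#' @param images H x W x 3 x N array (when the 2D branch is active).
#' @param features N x L matrix (when the 1D branch is active); the
#'   training standardization is applied. If the matrix carries a feature
#'   configuration attribute it must match the one used at fit time.
#' @param type `"class"` (argmax, ties to the lowest class index) or
#'   `"prob"`.
#' @param batch_size forward batch size.
#' @param .prescaled internal: features are already standardized.
#' @param ... unused.
#' @return a factor of predicted classes, or an N x K probability matrix.
#' @export
predict.sdnet <- function(object, images = NULL, features = NULL,
                          type = c("class", "prob"), batch_size = 32,
                          .prescaled = FALSE, ...) {
  type <- match.arg(type)
  config <- object$config
  n <- if (!is.null(images)) dim(images)[4] else if (!is.null(features))
    nrow(features) else 0L
  if (n == 0L) {
    return(if (type == "prob")
      matrix(0, 0, config$num_classes,
             dimnames = list(NULL, object$classes))
      else factor(character(0), levels = object$classes))
  }
  if ("2d" %in% config$branches && is.null(images)) stop("model needs images")
  if ("1d" %in% config$branches && is.null(features)) stop("model needs features")
  if (!is.null(features)) {
    fc <- attr(features, "config")
    if (!is.null(fc) && !is.null(object$feature_config) &&
        !identical(unclass(fc), unclass(object$feature_config)))
      stop("feature configuration differs from the one used to train the model")
    features <- as.matrix(features)
    if (ncol(features) != config$vector_length)
      stop("feature length ", ncol(features), " does not match the model (",
           config$vector_length, ")")
    if (!.prescaled && !is.null(object$scaling))
      features <- sweep(sweep(features, 2L, object$scaling$center),
                        2L, object$scaling$scale, `/`)
  }
  probs <- matrix(0, n, config$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    fw <- sdnet_forward(object$params, object$buffers, config,
                        if (!is.null(images)) images[, , , ids, drop = FALSE],
                        if (!is.null(features)) features[ids, , drop = FALSE],
                        training = FALSE)
    probs[ids, ] <- fw$probs
  }
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.sdnet <- function(x, ...) {
  cat("Dual-branch convolutional skin-image classifier\n")
  cat("  branches:", paste(x$config$branches, collapse = " + "), "\n")
  cat("  classes: ", paste(x$classes, collapse = ", "), "\n")
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  if (!is.null(x$history)) {
    last <- tail(x$history, 1L)
    cat(sprintf("  trained %d epochs; final loss %.4f, train accuracy %.3f\n",
                nrow(x$history), last$loss, last$accuracy))
  }
  if (!is.null(x$test))
    cat(sprintf("  held-out accuracy: %.3f (n = %d)\n", x$test$accuracy,
                length(x$test$indices)))
  invisible(x)
}

#' @export
summary.sdnet <- function(object, ...) {
  tab <- sdnet_param_table(object$config)
  print(object)
  cat("\nLayer table:\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' @export
coef.sdnet <- function(object, ...) object$params

#' @export
plot.sdnet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss", ...)
  plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
       ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}
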