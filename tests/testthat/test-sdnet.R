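test_that("branch shape algebra reproduces the printed architecture", {
  tab <- sdnet_param_table(table2_config())
  flat <- attr(tab, "flatten")
  expect_equal(unname(flat["2d"]), 262144)
  expect_equal(unname(flat["1d"]), 1106944)
  expect_equal(sum(flat), 1369088)
  p <- function(sub) tab$params[tab$sublayer == sub]
  expect_equal(p("Conv2D_1"), 1792)
  expect_equal(p("Conv2D_2"), 73856)
  expect_equal(p("Conv2D_3"), 295168)
  expect_equal(p("Conv1D_1"), 256)
  expect_equal(tab$params[tab$model == "2D-CNN" & tab$sublayer == "BatchNorm_1"], 128)
  expect_equal(p("FullyConnected"), 5476352)
})

test_that("parameter counts follow the closed-form layer formulas", {
  set.seed(42)
  for (rep in 1:5) {
    f2 <- sample(4:32, 3); f1 <- sample(4:32, 3)
    k <- sample(2:6, 1); vl <- sample(c(64, 100, 256), 1)
    cfg <- sdnet_config(num_classes = k, image_size = c(32, 32),
                        vector_length = vl, conv2d_filters = f2,
                        conv1d_filters = f1, fc_bias = TRUE)
    tab <- sdnet_param_table(cfg)
    cin <- c(3, f2[1:2])
    expect_equal(tab$params[grepl("Conv2D", tab$sublayer)],
                 9 * cin * f2 + f2)
    cin1 <- c(1, f1[1:2])
    expect_equal(tab$params[grepl("Conv1D", tab$sublayer)],
                 3 * cin1 * f1 + f1)
    expect_equal(tab$params[grepl("BatchNorm", tab$sublayer)],
                 2 * c(f2, f1))
    d <- sum(attr(tab, "flatten"))
    expect_equal(tab$params[tab$sublayer == "FullyConnected"], d * k + k)
    # the actual initialized tensors agree with the accounting
    init <- dermatex:::sdnet_init(cfg, seed = 1)
    expect_equal(sum(vapply(init$params, length, 1L)), attr(tab, "total"))
  }
})

test_that("odd pooled lengths round down as in the printed 1D stack", {
  tab <- sdnet_param_table(table2_config())
  out1d <- tab$output[tab$model == "1D-CNN"]
  expect_true(any(grepl("^17298", out1d)))
  expect_true(any(grepl("^8649", out1d)))
  expect_true(any(grepl("^4324", out1d)))
})

make_toy <- function(n = 20, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  imgs <- array(0, c(16, 16, 3, n))
  feats <- matrix(rnorm(n * 16, 0, 0.1), n, 16)
  for (i in seq_len(n)) {
    v <- if (y[i] == "a") 0.2 else 0.8
    imgs[, , , i] <- v + array(rnorm(16 * 16 * 3, 0, 0.05), c(16, 16, 3))
    feats[i, 1:4] <- if (y[i] == "a") -1 else 1
  }
  list(imgs = imgs, feats = feats, y = factor(y))
}

toy_config <- function(branches = c("2d", "1d")) {
  sdnet_config(num_classes = 2, image_size = c(16, 16), vector_length = 16,
               conv2d_filters = c(4, 8, 8), conv1d_filters = c(4, 8, 8),
               branches = branches)
}

test_that("forward pass yields valid, deterministic probability vectors", {
  toy <- make_toy()
  init <- dermatex:::sdnet_init(toy_config(), seed = 5)
  fw1 <- dermatex:::sdnet_forward(init$params, init$buffers, toy_config(),
                                  toy$imgs[, , , 1:4, drop = FALSE],
                                  toy$feats[1:4, ], training = FALSE)
  expect_equal(dim(fw1$probs), c(4, 2))
  expect_true(all(fw1$probs >= 0))
  expect_equal(rowSums(fw1$probs), rep(1, 4), tolerance = 1e-6)
  fw2 <- dermatex:::sdnet_forward(init$params, init$buffers, toy_config(),
                                  toy$imgs[, , , 1:4, drop = FALSE],
                                  toy$feats[1:4, ], training = FALSE)
  expect_identical(fw1$probs, fw2$probs)
})

test_that("freshly initialized models predict close to uniform on average", {
  set.seed(9)
  n <- 64
  imgs <- array(runif(16 * 16 * 3 * n), c(16, 16, 3, n))
  feats <- matrix(rnorm(n * 16), n, 16)
  cfg <- sdnet_config(num_classes = 5, image_size = c(16, 16),
                      vector_length = 16, conv2d_filters = c(4, 8, 8),
                      conv1d_filters = c(4, 8, 8))
  mean_probs <- matrix(0, 3, 5)
  for (s in 1:3) {
    init <- dermatex:::sdnet_init(cfg, seed = s)
    fw <- dermatex:::sdnet_forward(init$params, init$buffers, cfg, imgs, feats,
                                   training = TRUE)
    mean_probs[s, ] <- colMeans(fw$probs)
  }
  expect_true(all(abs(colMeans(mean_probs) - 0.2) < 0.15))
})

test_that("training overfits a separable toy set and is seed-reproducible", {
  toy <- make_toy()
  fit <- sdnet(toy$imgs, toy$feats, toy$y, config = toy_config(),
               epochs = 30, batch_size = 8, seed = 3)
  expect_equal(tail(fit$history$accuracy, 1), 1)
  expect_lt(tail(fit$history$loss, 1), 0.5 * fit$history$loss[1])
  expect_true(all(diff(fit$history$loss[c(1, 10, 30)]) < 0))
  fit2 <- sdnet(toy$imgs, toy$feats, toy$y, config = toy_config(),
                epochs = 5, batch_size = 8, seed = 3)
  fit3 <- sdnet(toy$imgs, toy$feats, toy$y, config = toy_config(),
                epochs = 5, batch_size = 8, seed = 3)
  expect_identical(fit2$history, fit3$history)
  expect_error(sdnet(toy$imgs, toy$feats, rep("a", 20), config = toy_config()),
               "two classes")
})

test_that("single-branch ablations are valid classifiers", {
  toy <- make_toy()
  f2d <- sdnet(images = toy$imgs, labels = toy$y,
               config = toy_config("2d"), epochs = 15, batch_size = 8, seed = 2)
  expect_equal(tail(f2d$history$accuracy, 1), 1)
  p <- predict(f2d, toy$imgs, type = "prob")
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
  f1d <- sdnet(features = toy$feats, labels = toy$y,
               config = toy_config("1d"), epochs = 40, batch_size = 8, seed = 2)
  expect_equal(tail(f1d$history$accuracy, 1), 1)
})

test_that("prediction takes the argmax with ties broken to the lowest index", {
  toy <- make_toy()
  fit <- sdnet(toy$imgs, toy$feats, toy$y, config = toy_config(),
               epochs = 2, batch_size = 8, seed = 1)
  p <- predict(fit, toy$imgs, toy$feats, type = "prob")
  cl <- predict(fit, toy$imgs, toy$feats, type = "class")
  expect_equal(as.integer(cl), unname(apply(p, 1, which.max)))
  # empty batch is vacuously fine
  empty <- predict(fit, toy$imgs[, , , 0, drop = FALSE],
                   toy$feats[0, , drop = FALSE])
  expect_length(empty, 0)
  expect_s3_class(empty, "factor")
  # tie-break contract on the probability row itself
  expect_equal(max.col(matrix(c(0.4, 0.4, 0.2), 1), ties.method = "first"), 1)
})

test_that("S3 methods print, summarize, and expose coefficients", {
  toy <- make_toy()
  fit <- sdnet(toy$imgs, toy$feats, toy$y, config = toy_config(),
               epochs = 2, batch_size = 8, seed = 1, split = 0.7)
  expect_output(print(fit), "held-out accuracy")
  expect_silent(tab <- withr::with_output_sink(tempfile(), summary(fit)))
  expect_s3_class(tab, "data.frame")
  expect_named(coef(fit)["fc.W"], "fc.W")
  expect_equal(nrow(fit$history), 2)
})
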