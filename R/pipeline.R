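# End-to-end experiment orchestration: synthesize (or load) a dataset,
# optionally enhance, extract handcrafted features, train the network
# variants, and report held-out metrics for every arm.

#' Experiment configuration
#'
#' Describes a complete synthetic-data experiment: the generator
#' conditions, the preprocessing arms to run, the model variants to train,
#' and the training schedule. Defaults give the reduced-scale five-class
#' recovery experiment (40 images per class at 32 x 32 with additive noise
#' 0.1).
#'
#' @param specs list of [class_texture_spec()] objects.
#' @param per_class images per class.
#' @param image_size training resolution `c(h, w)`.
#' @param noise_sigma,blur_sigma degradation applied by the generator.
#' @param preprocessing logical vector of arms to run: `TRUE` enhances
#'   images (and the grayscale the features are computed on) before
#'   training.
#' @param models subset of `c("sdnet", "2d", "1d")` to train per arm.
#' @param feature_config a [feature_config()].
#' @param ictef an [ictef_config()].
#' @param epochs,batch_size,lr,decay_rate,decay_every,split training
#'   schedule passed to [sdnet()].
#' @param seed master seed for generation, splitting, and training.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(specs = default_texture_specs(), per_class = 40,
                            image_size = c(32, 32), noise_sigma = 0.1,
                            blur_sigma = NULL,
                            preprocessing = c(TRUE, FALSE),
                            models = c("sdnet", "2d", "1d"),
                            feature_config = dermatex::feature_config(),
                            ictef = ictef_config(),
                            epochs = 30, batch_size = 16, lr = 0.001,
                            decay_rate = 0.5, decay_every = 10,
                            split = 0.7, seed = 1) {
  stopifnot(length(specs) >= 2, per_class >= 1,
            all(models %in% c("sdnet", "2d", "1d")), length(models) >= 1)
  structure(list(specs = specs, per_class = per_class,
                 image_size = as.integer(image_size),
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 preprocessing = preprocessing, models = models,
                 feature_config = feature_config, ictef = ictef,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 decay_rate = decay_rate, decay_every = decay_every,
                 split = split, seed = seed),
            class = "pipeline_config")
}

#' Enhance every image of a batch
#'
#' @param images H x W x 3 x N array.
#' @param config an [ictef_config()].
#' @return array of the same shape.
#' @export
enhance_dataset <- function(images, config = ictef_config()) {
  out <- images
  for (i in seq_len(dim(images)[4])) out[, , , i] <- ictef_enhance(images[, , , i], config)
  out
}

train_variant <- function(variant, images, features, labels, cfg) {
  branches <- switch(variant, sdnet = c("2d", "1d"), `2d` = "2d", `1d` = "1d")
  model_cfg <- sdnet_config(
    num_classes = nlevels(labels),
    image_size = dim(images)[1:2],
    vector_length = ncol(features),
    branches = branches)
  sdnet(images = if ("2d" %in% branches) images,
        features = if ("1d" %in% branches) features,
        labels = labels, config = model_cfg,
        epochs = cfg$epochs, batch_size = cfg$batch_size, lr = cfg$lr,
        decay_rate = cfg$decay_rate, decay_every = cfg$decay_every,
        split = cfg$split, seed = cfg$seed)
}

#' Run a full with/without-preprocessing experiment
#'
#' Generates the synthetic dataset, then for each requested preprocessing
#' arm extracts handcrafted features (from the enhanced grayscale in the
#' enhanced arm), trains the requested model variants with a stratified
#' train/test split, and collects held-out metrics. Identical
#' configuration and seed give an identical report.
#'
#' @param config a [pipeline_config()].
#' @param keep_models also return the fitted `sdnet` objects (default
#'   `FALSE`; reports stay serializable).
#' @return a list of class `experiment_report`: `config_snapshot`, and
#'   `arms`, a named list (`with_preprocessing` / `without_preprocessing`)
#'   whose elements map model variant to accuracy, confusion matrix, and
#'   metric summaries.
#' @export
run_experiment <- function(config = pipeline_config(), keep_models = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- generate_dataset(config$specs, per_class = config$per_class,
                         size = config$image_size,
                         noise_sigma = config$noise_sigma,
                         blur_sigma = config$blur_sigma, seed = config$seed)
  arms <- list(); models_out <- list()
  for (prep in config$preprocessing) {
    arm_name <- if (prep) "with_preprocessing" else "without_preprocessing"
    imgs <- if (prep) enhance_dataset(ds$images, config$ictef) else ds$images
    feats <- extract_feature_matrix(imgs, config$feature_config)
    arm <- list()
    for (variant in config$models) {
      fit <- train_variant(variant, imgs, feats, ds$labels, config)
      cc <- confusion_counts(fit$test$truth, fit$test$predicted)
      mr <- classification_metrics(cc)
      arm[[variant]] <- list(
        accuracy = fit$test$accuracy,
        confusion = unname(cc$matrix),
        macro = as.list(mr$macro),
        micro = as.list(mr$micro),
        final_train_loss = tail(fit$history$loss, 1L),
        final_train_accuracy = tail(fit$history$accuracy, 1L))
      if (keep_models) models_out[[paste(arm_name, variant, sep = ".")]] <- fit
    }
    arms[[arm_name]] <- arm
  }
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  report <- list(config_snapshot = strip_classes(config),
                 classes = levels(ds$labels),
                 n_images = length(ds$labels),
                 arms = arms)
  if (keep_models) attr(report, "models") <- models_out
  structure(report, class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment on", x$n_images, "images,",
      length(x$classes), "classes\n")
  for (arm in names(x$arms)) {
    cat(" ", arm, "\n")
    for (m in names(x$arms[[arm]]))
      cat(sprintf("    %-6s held-out accuracy %.3f\n", m,
                  x$arms[[arm]][[m]]$accuracy))
  }
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' @param report an `experiment_report` (or any serializable list).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
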