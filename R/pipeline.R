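#' Pipeline configuration
#'
#' Collects every stage parameter with its documented default. Unknown
#' arguments are rejected (R errors on unused arguments), so typos
#' cannot silently fall back to defaults.
#'
#' @param alpha,gamma sigmoid enhancement center/width on the 8-bit
#'   intensity scale. The pipeline defaults center the sigmoid
#'   mid-range (128, width 32), which boosts lesion/background contrast
#'   on typical images; a center far below the occupied intensity range
#'   saturates the image and destroys the contrast the later stages
#'   need.
#' @param kernel median kernel size. Default 3.
#' @param diff_iters,kappa,step anisotropic-diffusion parameters.
#'   Defaults 15, 30, 0.2.
#' @param M,fuzzifier clustering parameters. Defaults 3, 2.
#' @param levelset_iters level-set budget. Default 200.
#' @param mu level-set curvature weight. Default 0.2.
#' @param roi_margin ROI margin in pixels. Default 8.
#' @param glcm_levels grey levels for texture features. Default 32.
#' @param retained_variance PCA retention target. Default 0.95.
#' @param tune run GWO hyperparameter tuning (`TRUE`) or train directly
#'   at `Z_default`. Default `TRUE`.
#' @param Z_default hidden neurons when not tuning. Default 8.
#' @param wolves,gwo_iters GWO population/iterations. Defaults 15, 30.
#' @param tune_epochs,final_epochs LM budgets during tuning / final
#'   retrain. Defaults 15, 60.
#' @param seed global seed; stage seeds are derived as `seed + 1`
#'   (split), `seed + 2` (tuning), `seed + 3` (weight init).
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(alpha = 128, gamma = 32, kernel = 3L,
                            diff_iters = 15L, kappa = 30, step = 0.2,
                            M = 3L, fuzzifier = 2, levelset_iters = 200L,
                            mu = 0.2, roi_margin = 8L, glcm_levels = 32L,
                            retained_variance = 0.95, tune = TRUE,
                            Z_default = 8L, wolves = 15L, gwo_iters = 30L,
                            tune_epochs = 15L, final_epochs = 60L,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Preprocess, segment and featurize a set of images
#'
#' Runs enhancement, despeckling, segmentation and feature extraction on
#' each image and assembles the feature table. Deterministic: the whole
#' stage contains no randomness.
#'
#' @param images list of numeric matrices (or `phantom_sample` objects,
#'   whose `$image` is used).
#' @param labels optional label vector (one per image); appended as a
#'   `label` column.
#' @param config a [pipeline_config()].
#' @return list with `features` (data.frame, one row per image, columns
#'   per [feature_schema()] plus `label`) and `masks` (list of refined
#'   masks).
#' @export
pipeline_features <- function(images, labels = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  imgs <- lapply(images, function(x) if (inherits(x, "phantom_sample")) x$image else x)
  masks <- vector("list", length(imgs))
  rows <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    pre <- preprocess_image(imgs[[i]], alpha = config$alpha,
                            gamma = config$gamma, kernel = config$kernel,
                            iterations = config$diff_iters,
                            kappa = config$kappa, step = config$step)
    seg <- segment_lesion(pre, M = config$M, fuzzifier = config$fuzzifier,
                          levelset_iters = config$levelset_iters,
                          mu = config$mu)
    roi <- extract_roi(seg$mask, pre, margin = config$roi_margin)
    rows[[i]] <- extract_features(roi$roi, roi$mask,
                                  levels = config$glcm_levels)
    masks[[i]] <- seg$mask
  }
  features <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(imgs))
    features$label <- as.character(labels)
  }
  list(features = features, masks = masks)
}

#' Train and evaluate the classifier on a feature table
#'
#' Stratified 70/30 split; standardization and PCA fitted on the
#' training rows only; GWO-tuned (or direct) Levenberg-Marquardt
#' training of the wavelet network; metrics and ROC on the held-out
#' test rows plus stratified cross-validation fold assignments.
#'
#' @param features data.frame from [pipeline_features()], with a
#'   `label` column.
#' @param config a [pipeline_config()].
#' @return list with `model`, `pca`, `standardizer`, `split`,
#'   `hyperparams`, `tune_report`, `train_metrics`, `test_metrics`,
#'   `roc`, `config`.
#' @export
pipeline_train <- function(features, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(features$label)) stop("`features` needs a label column", call. = FALSE)
  labels <- features$label
  x_raw <- features[, setdiff(names(features), "label"), drop = FALSE]
  plan <- split_and_cv(labels, seed = config$seed + 1L, quiet = TRUE)
  std <- standardize_fit(x_raw[plan$train_idx, , drop = FALSE])
  x_tr <- standardize_apply(x_raw[plan$train_idx, , drop = FALSE], std)
  x_te <- standardize_apply(x_raw[plan$test_idx, , drop = FALSE], std)
  pca <- pca_fit_transform(x_tr, retained_variance = config$retained_variance)
  z_tr <- pca$scores
  z_te <- pca_transform(pca$model, x_te)
  y_tr <- as_binary_labels(labels[plan$train_idx])
  tune_report <- NULL; hyperparams <- NULL
  if (isTRUE(config$tune)) {
    tuned <- tune_wnn(z_tr, labels[plan$train_idx], S = config$wolves,
                      I_max = config$gwo_iters, seed = config$seed + 2L,
                      tune_epochs = config$tune_epochs,
                      final_epochs = config$final_epochs)
    model <- tuned$model
    tune_report <- tuned$report
    hyperparams <- tuned$hyperparams
  } else {
    model <- wnn_init(ncol(z_tr), config$Z_default, seed = config$seed + 3L,
                      X = z_tr)
    model <- lm_train(model, z_tr, y_tr, max_epochs = config$final_epochs)
    hyperparams <- list(Z = config$Z_default, lambda0 = 1e-2,
                        init_scale = 1 / sqrt(ncol(z_tr)))
  }
  pred_tr <- predict(model, z_tr)
  pred_te <- predict(model, z_te)
  test_labels <- labels[plan$test_idx]
  list(model = model, pca = pca$model, standardizer = std, split = plan,
       hyperparams = hyperparams, tune_report = tune_report,
       train_metrics = metrics(confusion(labels[plan$train_idx], pred_tr$class)),
       test_metrics = metrics(confusion(test_labels, pred_te$class)),
       roc = roc_auc(test_labels, pred_te$score),
       config = config)
}

#' Run the full pipeline end to end
#'
#' Preprocess, segment, featurize, then train and evaluate. Re-running
#' with an identical config and inputs reproduces the metrics exactly.
#'
#' @param images list of numeric matrices or `phantom_sample` objects.
#' @param labels label vector (`"benign"`/`"malignant"`).
#' @param config a [pipeline_config()].
#' @return the [pipeline_train()] result, plus `features` and `masks`.
#' @export
run_pipeline <- function(images, labels, config = pipeline_config()) {
  feats <- pipeline_features(images, labels, config)
  out <- pipeline_train(feats$features, config)
  out$features <- feats$features
  out$masks <- feats$masks
  out
}

#' Save pipeline artifacts in a fixed layout
#'
#' Writes `masks/` (PNG), `features.csv`, `model.json`, `metrics.json`,
#' `roc.csv`, `run.log` and `manifest.csv` (every written file with its
#' md5 checksum) under `outdir`. Refuses to overwrite existing artifacts
#' unless `overwrite = TRUE`.
#'
#' @param result a [run_pipeline()] result.
#' @param outdir destination directory.
#' @param overwrite allow overwriting existing artifacts. Default
#'   `FALSE`.
#' @return invisibly, the manifest data.frame.
#' @export
save_results <- function(result, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) &&
      length(list.files(outdir, recursive = TRUE)) > 0 && !overwrite) {
    stop(sprintf("output directory %s is not empty (use overwrite = TRUE)",
                 outdir), call. = FALSE)
  }
  dir.create(file.path(outdir, "masks"), recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (!is.null(result$masks)) {
    for (i in seq_along(result$masks)) {
      p <- file.path(outdir, "masks", sprintf("mask_%03d.png", i))
      save_mask(result$masks[[i]], p)
      written <- c(written, p)
    }
  }
  if (!is.null(result$features)) {
    p <- file.path(outdir, "features.csv")
    write.csv(result$features, p, row.names = FALSE)
    written <- c(written, p)
  }
  p <- file.path(outdir, "model.json"); wnn_save(result$model, p)
  written <- c(written, p)
  p <- file.path(outdir, "metrics.json")
  jsonlite::write_json(list(seed = result$config$seed,
                            hyperparams = result$hyperparams,
                            train = unclass(result$train_metrics),
                            test = unclass(result$test_metrics),
                            auc = result$roc$auc),
                       p, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, p)
  p <- file.path(outdir, "roc.csv")
  write.csv(result$roc$curve, p, row.names = FALSE)
  written <- c(written, p)
  p <- file.path(outdir, "run.log")
  writeLines(c(sprintf("uscad %s", as.character(utils::packageVersion("uscad"))),
               sprintf("seed: %d", result$config$seed),
               sprintf("config: %s",
                       paste(deparse(unclass(result$config)), collapse = " "))),
             p)
  written <- c(written, p)
  manifest <- data.frame(file = written, md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
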