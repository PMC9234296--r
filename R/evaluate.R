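# Canonicalize labels to 0 (benign) / 1 (malignant).
as_binary_labels <- function(x, arg = "labels") {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- !x %in% c("benign", "malignant")
    if (any(bad)) {
      stop(sprintf("unknown %s value: %s", arg, x[which(bad)[1]]), call. = FALSE)
    }
    return(as.integer(x == "malignant"))
  }
  if (is.numeric(x) || is.logical(x)) {
    x <- as.integer(x)
    if (!all(x %in% c(0L, 1L))) {
      stop(sprintf("numeric %s must be 0/1", arg), call. = FALSE)
    }
    return(x)
  }
  stop(sprintf("cannot interpret %s", arg), call. = FALSE)
}

#' Confusion matrix (malignant = positive)
#'
#' Counts with the convention that malignant is the positive class:
#' a correctly identified malignant lesion is a true positive, a
#' correctly identified benign lesion a true negative.
#'
#' @param labels true labels (`"benign"`/`"malignant"`, or 0/1 with 1 =
#'   malignant).
#' @param predictions predicted labels, same encoding and length.
#' @return object of class `confusion`: named vector `TP, FP, FN, TN`.
#' @export
confusion <- function(labels, predictions) {
  y <- as_binary_labels(labels, "labels")
  p <- as_binary_labels(predictions, "predictions")
  if (length(y) != length(p)) stop("length mismatch", call. = FALSE)
  structure(c(TP = sum(y == 1 & p == 1), FP = sum(y == 0 & p == 1),
              FN = sum(y == 1 & p == 0), TN = sum(y == 0 & p == 0)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(x[c("TP", "FN", "FP", "TN")], 2, 2, byrow = TRUE,
              dimnames = list(truth = c("malignant", "benign"),
                              predicted = c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`, and each cell as a
#' fraction of the total. Fields with a zero denominator are reported as
#' `NA` (undefined), never silently 0.
#'
#' @param cm a [confusion()] result (or named TP/FP/FN/TN vector).
#' @return object of class `metrics_report`: named list of raw
#'   fractions.
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(cm)))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    accuracy = (cm[["TP"]] + cm[["TN"]]) / n,
    sensitivity = safe(cm[["TP"]], cm[["TP"]] + cm[["FN"]]),
    specificity = safe(cm[["TN"]], cm[["TN"]] + cm[["FP"]]),
    ppv = safe(cm[["TP"]], cm[["TP"]] + cm[["FP"]]),
    npv = safe(cm[["TN"]], cm[["TN"]] + cm[["FN"]]),
    tp_fraction = cm[["TP"]] / n,
    fp_fraction = cm[["FP"]] / n,
    fn_fraction = cm[["FN"]] / n,
    tn_fraction = cm[["TN"]] / n,
    n = n)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  # display rounding: whole percent for accuracy, one decimal elsewhere;
  # the stored values are always the raw fractions
  cat(sprintf("accuracy     %.0f%%\n", 100 * x$accuracy))
  for (f in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("%-12s %s\n", f,
                if (is.na(x[[f]])) "undefined" else sprintf("%.1f%%", 100 * x[[f]])))
  }
  cat(sprintf("TP/TN fractions %.1f%% / %.1f%% of n=%d\n",
              100 * x$tp_fraction, 100 * x$tn_fraction, x$n))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores to build the ROC
#' curve, and computes AUC with the Mann-Whitney pair statistic (each
#' benign-malignant pair contributes 1 if the malignant score is higher,
#' 1/2 on ties). On ties-free data the trapezoidal area under the swept
#' curve equals the pair statistic exactly.
#'
#' @param labels true labels (both classes must be present).
#' @param scores numeric scores, higher = more malignant.
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- do.call(rbind, lapply(thr, function(th) {
    pred <- scores >= th
    data.frame(threshold = th,
               fpr = sum(pred & y == 0) / n_neg,
               tpr = sum(pred & y == 1) / n_pos)
  }))
  r <- rank(scores)  # average ranks give ties half credit
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(curve = curve, auc = auc)
}

#' Stratified 70/30 split and cross-validation folds
#'
#' Builds a stratified train/test split and stratified k-fold
#' assignments, deterministic given the seed. Class ratios are preserved
#' within one sample per fold. If the smaller class has fewer samples
#' than `folds`, the fold count is reduced with a warning.
#'
#' @param labels class labels.
#' @param seed RNG seed.
#' @param train_frac training fraction. Default 0.7.
#' @param folds requested fold count. Default 10.
#' @param quiet suppress the fold-reduction warning.
#' @return object of class `split_plan`: `train_idx`, `test_idx`,
#'   `fold` (per-sample fold id), `folds`, `seed`.
#' @export
split_and_cv <- function(labels, seed = 1L, train_frac = 0.7, folds = 10L,
                         quiet = FALSE) {
  y <- as_binary_labels(labels)
  n <- length(y)
  folds <- as.integer(folds)
  min_class <- min(table(y))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    if (!quiet) {
      warning(sprintf("smallest class has %d samples; reducing to %d folds",
                      min_class, folds))
    }
  }
  with_seed(seed, {
    train_idx <- integer(0)
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      n_tr <- round(train_frac * length(idx))
      train_idx <- c(train_idx, idx[seq_len(n_tr)])
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    train_idx <- sort(train_idx)
    structure(list(train_idx = train_idx,
                   test_idx = setdiff(seq_len(n), train_idx),
                   fold = fold, folds = folds, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d train / %d test, %d folds, seed %d\n",
              length(x$train_idx), length(x$test_idx), x$folds, x$seed))
  invisible(x)
}
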