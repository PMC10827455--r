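#' Confusion matrix for the two-class problem
#'
#' Integer 2x2 matrix, rows = true class, columns = predicted class, in
#' (benign, malignant) order; the off-diagonal sum is the misclassification
#' count.
#'
#' @param true_labels,predicted_labels equal-length vectors with values in
#'   `benign`/`malignant`.
#' @return A 2x2 integer matrix.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    abort("label vectors must have equal length")
  tt <- table(true = as_class_factor(true_labels),
              predicted = as_class_factor(predicted_labels))
  m <- matrix(as.integer(tt), 2L, 2L,
              dimnames = list(true = CLASS_LEVELS, predicted = CLASS_LEVELS))
  m
}

#' Accuracy and F1 from a confusion matrix
#'
#' Standard definitions: accuracy = trace/sum; per-class
#' `F1 = 2PR/(P + R)` with the class taken as positive; macro-F1 is their
#' unweighted mean. A zero denominator in precision, recall or F1 yields 0
#' with a warning.
#'
#' @param confusion 2x2 matrix from [confusion_matrix()].
#' @return A one-row tibble: `accuracy`, `f1_benign`, `f1_malignant`,
#'   `macro_f1`.
#' @export
classification_metrics <- function(confusion) {
  if (!all(dim(confusion) == c(2L, 2L)) || any(confusion < 0))
    abort("`confusion` must be a non-negative 2x2 matrix")
  n <- sum(confusion)
  acc <- if (n > 0) sum(diag(confusion)) / n else 0
  f1 <- vapply(1:2, function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[-k, k])
    fn <- sum(confusion[k, -k])
    if (2 * tp + fp + fn == 0) {
      warn(sprintf("F1 undefined for class '%s' (no true or predicted positives); reported as 0",
                   CLASS_LEVELS[k]))
      return(0)
    }
    if (tp == 0 && (fp > 0 || fn > 0) && (tp + fp == 0 || tp + fn == 0))
      warn(sprintf("precision or recall undefined for class '%s'; F1 reported as 0",
                   CLASS_LEVELS[k]))
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  tibble::tibble(accuracy = acc, f1_benign = f1[1], f1_malignant = f1[2],
                 macro_f1 = mean(f1))
}

# ROC curve and trapezoidal AUC for one positive class. Midpoint tie
# handling makes the trapezoid equal the Mann-Whitney pair statistic.
roc_curve_one <- function(scores, positive_truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive_truth[ord]
  np <- sum(y); nn <- sum(!y)
  # collapse tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(points = tibble::tibble(fpr = fpr, tpr = tpr), auc = auc)
}

#' ROC points and AUC per class
#'
#' Threshold sweep over the predicted class-probability scores with
#' trapezoidal integration; ties are handled at their midpoint, so the AUC
#' equals the Mann-Whitney concordant-pair statistic. The benign-class
#' curve uses `1 - score` as the benign score. Single-class truth yields
#' `NaN` AUCs with a warning.
#'
#' @param scores per-sample probability of the malignant class, in `[0, 1]`.
#' @param true_labels class labels aligned with `scores`.
#' @return A list: `roc_points` (tibble: class, fpr, tpr; each curve runs
#'   from (0,0) to (1,1)) and `auc_per_class` (named vector).
#' @export
roc_auc <- function(scores, true_labels) {
  if (any(scores < 0 | scores > 1)) abort("`scores` must lie in [0, 1]")
  f <- as_class_factor(true_labels)
  if (length(unique(f)) < 2L) {
    warn("single-class truth: AUC undefined, reported as NaN")
    return(list(roc_points = tibble::tibble(class = character(), fpr = double(),
                                            tpr = double()),
                auc_per_class = c(benign = NaN, malignant = NaN)))
  }
  rm_ <- roc_curve_one(scores, f == "malignant")
  rb <- roc_curve_one(1 - scores, f == "benign")
  list(
    roc_points = dplyr::bind_rows(
      dplyr::mutate(rb$points, class = "benign", .before = 1L),
      dplyr::mutate(rm_$points, class = "malignant", .before = 1L)),
    auc_per_class = c(benign = rb$auc, malignant = rm_$auc)
  )
}

#' Evaluate a model on labeled images
#'
#' Inference-mode predictions, confusion matrix, accuracy/F1 and per-class
#' ROC-AUC, optionally restricted to one magnification tier.
#'
#' @param model `model_graph`.
#' @param x `(H, W, 3, N)` images.
#' @param true_labels class labels aligned with `x`.
#' @param magnification tier label stored on the report (`"all"` by
#'   default).
#' @return An object of class `eval_report`: list with `magnification`,
#'   `n`, `confusion`, `metrics` (tibble), `roc_points`, `auc_per_class`.
#' @export
evaluate_model <- function(model, x, true_labels, magnification = "all") {
  pr <- predict_proba(model, x)
  eval_report(true_labels, pr$predicted_label, pr$malignant, magnification)
}

#' Build an evaluation report from predictions
#'
#' @param true_labels,predicted_labels class labels.
#' @param scores malignant-class probabilities (optional; without them the
#'   ROC/AUC fields are omitted).
#' @param magnification tier label for the report.
#' @return An `eval_report`.
#' @export
eval_report <- function(true_labels, predicted_labels, scores = NULL,
                        magnification = "all") {
  cm <- confusion_matrix(true_labels, predicted_labels)
  metrics <- classification_metrics(cm)
  roc <- if (!is.null(scores)) roc_auc(scores, true_labels)
  structure(list(magnification = as.character(magnification),
                 n = sum(cm), confusion = cm, metrics = metrics,
                 roc_points = roc$roc_points,
                 auc_per_class = roc$auc_per_class),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report magnification=%s n=%d>\n", x$magnification, x$n))
  print(x$confusion)
  print(x$metrics)
  if (!is.null(x$auc_per_class))
    cat(sprintf("AUC benign %.4f / malignant %.4f\n",
                x$auc_per_class[["benign"]], x$auc_per_class[["malignant"]]))
  invisible(x)
}

#' Magnification-stratified summary table
#'
#' One row per tier with accuracy, F1 and AUC, projected field-by-field
#' from the individual reports. Tiers missing from `reports` are omitted
#' with a warning.
#'
#' @param reports list of `eval_report`s (typically one per tier).
#' @param expected_tiers tiers expected to be present.
#' @return A tibble: `magnification`, `n`, `accuracy`, `f1_benign`,
#'   `f1_malignant`, `macro_f1`, `auc_benign`, `auc_malignant`.
#' @export
magnification_report <- function(reports,
                                 expected_tiers = as.character(MAGNIFICATIONS)) {
  have <- vapply(reports, `[[`, "", "magnification")
  missing <- setdiff(expected_tiers, have)
  if (length(missing) > 0L)
    warn(paste0("missing magnification tier(s): ", paste(missing, collapse = ", ")))
  purrr::map_dfr(reports, function(r) {
    dplyr::bind_cols(
      tibble::tibble(magnification = r$magnification, n = r$n),
      r$metrics,
      tibble::tibble(
        auc_benign = if (is.null(r$auc_per_class)) NA_real_ else r$auc_per_class[["benign"]],
        auc_malignant = if (is.null(r$auc_per_class)) NA_real_ else r$auc_per_class[["malignant"]]))
  })
}

#' Export an evaluation report as JSON
#'
#' @param report `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(list(
    magnification = report$magnification, n = report$n,
    confusion = report$confusion, metrics = as.list(report$metrics),
    auc_per_class = as.list(report$auc_per_class)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
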