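#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives against expert truth, with
#' class 1 = particle binding present.
#'
#' @param predictions Integer/numeric vector of 0/1 predictions.
#' @param truth Integer/numeric vector of 0/1 labels, same length.
#' @return A tibble with one row: `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
#' @examples
#' confusion(c(1, 0, 1), c(1, 0, 0))
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1L) {
    abort("`predictions` and `truth` must have equal length >= 1.",
      class = "patchfreq_bad_input"
    )
  }
  if (!all(predictions %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    abort("Predictions and truth must be 0/1.", class = "patchfreq_bad_label")
  }
  tibble::tibble(
    tp = sum(predictions == 1 & truth == 1),
    fp = sum(predictions == 1 & truth == 0),
    fn = sum(predictions == 0 & truth == 1),
    tn = sum(predictions == 0 & truth == 0),
    n = length(truth)
  )
}

metric_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(
      paste0(what, " is undefined: zero denominator."),
      class = "patchfreq_undefined_metric"
    )
    return(NA_real_)
  }
  num / den
}

#' Precision, recall and accuracy from confusion counts
#'
#' The standard ratios: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' accuracy `(TP+TN)/n`. A zero denominator yields `NA` together with a
#' classed warning (`patchfreq_undefined_metric`) rather than a silent 0,
#' so degenerate evaluations cannot masquerade as poor-but-valid scores.
#' Accuracy summarizes performance faithfully only when the two classes
#' are balanced; inspect precision and recall otherwise.
#'
#' @param counts One-row tibble from [confusion()] (columns `tp`, `fp`,
#'   `fn`, `tn`).
#' @return Scalar in \[0, 1\], or `NA` if undefined.
#' @export
#' @examples
#' precision(confusion(c(1, 0), c(1, 0)))
precision <- function(counts) {
  metric_ratio(counts$tp, counts$tp + counts$fp, "Precision")
}

#' @rdname precision
#' @export
recall <- function(counts) {
  metric_ratio(counts$tp, counts$tp + counts$fn, "Recall")
}

#' @rdname precision
#' @export
accuracy <- function(counts) {
  metric_ratio(
    counts$tp + counts$tn,
    counts$tp + counts$fp + counts$fn + counts$tn, "Accuracy"
  )
}

#' Evaluate a model on a labelled feature table
#'
#' Predicts on `table` and reports confusion counts plus the three summary
#' metrics in one tidy row.
#'
#' @param model A `patchfreq_tree` or `patchfreq_forest`.
#' @param table Feature table with a `label` column.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `n`, `precision`,
#'   `recall`, `accuracy`.
#' @export
evaluate_model <- function(model, table) {
  check_feature_table(table)
  if (!"label" %in% names(table)) {
    abort("Evaluation requires a `label` column.",
      class = "patchfreq_bad_label"
    )
  }
  pred <- predict(model, table)
  counts <- confusion(pred, table$label)
  dplyr::mutate(
    counts,
    precision = precision(counts),
    recall = recall(counts),
    accuracy = accuracy(counts)
  )
}
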