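#' Confusion counts at a threshold
#'
#' A score at or above the threshold predicts the positive class (ties
#' predict positive).
#'
#' @param labels Binary vector (1 = positive).
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Classification threshold (default 0.5).
#' @return Named list `tp`, `fp`, `tn`, `fn`; the four counts partition the
#'   input.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1L & labels == 1L),
       fp = sum(pred == 1L & labels == 0L),
       tn = sum(pred == 0L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L))
}

#' Area under the ROC curve
#'
#' Computed in the rank-statistic form: the probability that a uniformly
#' random positive outscores a uniformly random negative, with ties counted
#' one half. This equals the trapezoidal area under the ROC curve.
#'
#' @param labels Binary vector (1 = positive); both classes must be present.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Matthews correlation coefficient from confusion counts
#'
#' Standard formula `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`;
#' if any factor of the denominator is zero the coefficient is defined as 0
#' (the usual degenerate-table convention).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc_score <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Evaluate scored predictions against binary labels
#'
#' Assembles the six classification metrics — AUC, accuracy (ACC),
#' sensitivity (SEN), specificity (SPE), precision (PRE) and Matthews
#' correlation coefficient (MCC) — plus the underlying confusion counts.
#'
#' @param labels Binary vector (1 = positive).
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Classification threshold (default 0.5).
#' @return A `cpp_metrics` object; see [glance.cpp_metrics()] for the
#'   one-row tibble form.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  cm <- confusion(labels, scores, threshold)
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    auc = auc_score(labels, scores),
    acc = safe_div(cm$tp + cm$tn, n),
    sen = safe_div(cm$tp, cm$tp + cm$fn),
    spe = safe_div(cm$tn, cm$tn + cm$fp),
    pre = safe_div(cm$tp, cm$tp + cm$fp),
    mcc = mcc_score(cm$tp, cm$fp, cm$tn, cm$fn),
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
    n = n, threshold = threshold
  ), class = "cpp_metrics")
}

#' @export
print.cpp_metrics <- function(x, ...) {
  cat(sprintf(
    "<cpp_metrics> n=%d thr=%.2f | AUC %.3f ACC %.3f SEN %.3f SPE %.3f PRE %.3f MCC %.3f\n",
    x$n, x$threshold, x$auc, x$acc, x$sen, x$spe, x$pre, x$mcc))
  invisible(x)
}

#' Write a metrics report to JSON and/or TSV
#'
#' @param metrics A `cpp_metrics` object.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return The metrics object, invisibly.
#' @export
write_metrics <- function(metrics, json_path = NULL, tsv_path = NULL) {
  row <- generics::glance(metrics)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(row), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(row, tsv_path, progress = FALSE)
  }
  invisible(metrics)
}

#' Peptide-level evaluation of an ensemble on labelled peptides
#'
#' Scores each peptide with the whole-peptide rule (mean over its 9-mer
#' windows) and evaluates against the labels. Window-level evaluation is
#' available by scoring fragments with [predict_windows()] and calling
#' [evaluate_predictions()] directly.
#'
#' @param peptides Data frame with columns `id`, `sequence`, `label`.
#' @param ensemble A `cpp_ensemble`.
#' @param threshold Classification threshold (default 0.5).
#' @return A `cpp_metrics` object with the scored peptide tibble attached
#'   as attribute `"scores"`.
#' @export
evaluate_peptides <- function(peptides, ensemble, threshold = 0.5) {
  scored <- score_peptides(peptides, ensemble)
  m <- evaluate_predictions(scored$label, scored$score, threshold)
  attr(m, "scores") <- scored
  m
}
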