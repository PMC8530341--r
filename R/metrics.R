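# Evaluation metrics: balanced accuracy, weighted kappa, ROC AUC.

#' Balanced accuracy
#'
#' Unweighted mean of per-class recall; reduces to
#' (sensitivity + specificity) / 2 in the binary case and generalizes to
#' multi-class as macro-recall.
#'
#' @param true,predicted vectors of class labels (same scale).
#' @param levels class levels to average over; defaults to the classes
#'   observed in `true`. A level with zero true cases raises an error.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(true, predicted, levels = NULL) {
  if (length(true) != length(predicted)) stop("length mismatch")
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (is.null(levels)) levels <- sort(unique(true))
  recalls <- vapply(as.character(levels), function(cl) {
    sel <- true == cl
    if (!any(sel)) stop("class with zero true cases: ", cl)
    mean(predicted[sel] == cl)
  }, numeric(1L))
  mean(recalls)
}

#' Weighted kappa for ordinal agreement
#'
#' Chance-corrected agreement `1 - sum(w * O) / sum(w * E)` with
#' disagreement weights `w_ij = |i - j| / (k - 1)` (linear, default) or its
#' square (quadratic), observed table `O` and expected table `E` from the
#' marginals.
#'
#' @param true,predicted integer-valued ordinal labels on a shared scale.
#' @param weights `"linear"` or `"quadratic"`.
#' @param levels ordinal levels of the shared scale; defaults to the sorted
#'   union of observed values.
#' @return Kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(true, predicted, weights = c("linear", "quadratic"),
                           levels = NULL) {
  weights <- match.arg(weights)
  if (length(true) != length(predicted)) stop("length mismatch")
  if (is.null(levels)) levels <- sort(unique(c(true, predicted)))
  k <- length(levels)
  if (k < 2L)
    stop("weighted kappa undefined: fewer than two distinct labels")
  ft <- factor(true, levels = levels)
  fp <- factor(predicted, levels = levels)
  obs <- table(ft, fp)
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1L)
  if (weights == "quadratic") w <- w^2
  1 - sum(w * obs) / sum(w * expected)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a positive case scores
#' above a random negative case, counting ties as one half.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
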