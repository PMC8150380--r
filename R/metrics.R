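#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted 1/2 — computed from average ranks, so it is
#' exact under ties.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1, logical, or a 2-level factor whose
#'   second level is the positive class... here: anything coercible with
#'   `as_binary_labels()`; both classes must be present).
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of precision over recall, evaluated at each distinct
#' score threshold in descending order with tied scores grouped:
#' `AP = sum_t precision(t) * (TP(t) - TP(t_prev)) / P`.
#'
#' @inheritParams roc_auc
#' @return average precision in `(0,1]`; errors when no positive labels.
#' @export
pr_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  P <- sum(y == 1)
  if (P == 0) stop("pr_auc needs at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp_at <- vapply(thr, function(t) sum(y == 1 & scores >= t), numeric(1))
  fp_at <- vapply(thr, function(t) sum(y == 0 & scores >= t), numeric(1))
  d_tp <- diff(c(0, tp_at))
  prec <- tp_at / (tp_at + fp_at)
  sum(prec * d_tp) / P
}

# Coerce labels to a 0/1 integer vector; accepts logical, 0/1 numeric, a
# factor/character with levels {essential, non_essential} or any two-level
# factor (first level = positive for essential/non_essential, otherwise the
# level named "1"/"TRUE"/second sorted level is positive).
as_binary_labels <- function(labels) {
  if (inherits(labels, "label_set")) {
    if (any(labels == "unlabeled")) stop("labels contain unlabeled genes; subset first")
    return(as.integer(labels == "essential"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else sort(unique(as.character(labels)))
  if (setequal(lv, c("essential", "non_essential")))
    return(as.integer(as.character(labels) == "essential"))
  if (length(lv) > 2) stop("labels must be binary")
  as.integer(as.character(labels) == lv[length(lv)])
}
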