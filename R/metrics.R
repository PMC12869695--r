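# Ranking metrics: AUROC (Mann-Whitney form, ties counted 1/2), AUPRC by
# step integration of the precision-recall curve, Spearman rank correlation.

check_two_class <- function(labels, what) {
  if (length(unique(labels)) < 2) {
    stopf("combisyn_metric_error",
          "%s needs both classes present in the labels", what)
  }
}

#' Ranking metrics
#'
#' `metric_auroc()` is the probability that a random positive outranks a
#' random negative, ties counted one half (the normalized Mann-Whitney U
#' statistic). `metric_auprc()` integrates the precision-recall curve by
#' steps (average precision; no trapezoids). `metric_spearman()` is the
#' Pearson correlation of average ranks.
#'
#' @param labels 0/1 vector (both classes required).
#' @param scores Numeric prediction scores.
#' @return A value in `[0, 1]` (`metric_spearman`: in `[-1, 1]`).
#' @export
#' @examples
#' metric_auroc(c(1, 0), c(0.9, 0.1))
metric_auroc <- function(labels, scores) {
  check_two_class(labels, "AUROC")
  pos <- labels == 1
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname metric_auroc
#' @export
metric_auprc <- function(labels, scores) {
  check_two_class(labels, "AUPRC")
  # group tied scores so the curve is order-independent
  ord <- order(-scores)
  labels <- labels[ord]; scores <- scores[ord]
  grp <- cumsum(!duplicated(scores))
  tp_g <- tapply(labels, grp, sum)
  n_g <- tapply(labels, grp, length)
  tp <- cumsum(tp_g); n <- cumsum(n_g)
  n_pos <- sum(labels)
  recall <- tp / n_pos
  precision <- tp / n
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' @rdname metric_auroc
#' @param x,y Numeric vectors (length >= 3) for the rank correlation.
#' @export
metric_spearman <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stopf("combisyn_metric_error",
          "Spearman correlation needs two equal-length vectors with n >= 3")
  }
  cor(rank(x), rank(y))
}
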