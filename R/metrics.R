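metric_error <- function(msg) abort(msg, class = "riskpipe_metric_error")

check_binary_metric_input <- function(scores, labels) {
  if (length(scores) != length(labels)) metric_error("scores and labels differ in length")
  if (any(is.na(scores)) || any(is.na(labels))) metric_error("NA in metric input")
  if (!all(labels %in% c(0, 1))) metric_error("labels must be 0/1")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    metric_error("metric undefined: need at least one case and one control")
  }
}

#' Area under the ROC curve (c-statistic)
#'
#' Computed by the rank (Mann-Whitney) identity: the probability that a
#' randomly chosen case outscores a randomly chosen control, with tied scores
#' counting one half. Invariant under strictly monotone score transforms.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(3, 2, 1), c(1, 0, 0)) # 1
#' @export
auroc <- function(scores, labels) {
  check_binary_metric_input(scores, labels)
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision over distinct score thresholds in descending order, with
#' tied scores entering as one group: `AP = sum_k (TP_k - TP_{k-1}) * P_k`
#' where `P_k` is precision after including the k-th tie group.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_binary_metric_input(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- as.integer(labels[o])
  grp_last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1 - y)[grp_last]
  d_tp <- diff(c(0, tp))
  sum(d_tp * tp / (tp + fp)) / sum(y)
}

#' Harrell's concordance index for right-censored survival data
#'
#' The probability, over admissible pairs, that the patient who experienced
#' the event earlier carried the higher risk score; tied scores count one
#' half, and pairs with equal event times are not comparable. The fast path
#' is the tree-based concordance computation of the survival package; a
#' brute-force pair scan serves as its independent oracle in the test suite.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(scores, times, events) {
  if (any(times < 0)) metric_error("times must be non-negative")
  if (sum(events) == 0) metric_error("c-index undefined: no events")
  cc <- survival::concordance(survival::Surv(times, events) ~ scores,
                              reverse = TRUE)
  unname(cc$concordance)
}
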