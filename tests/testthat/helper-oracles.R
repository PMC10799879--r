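# Independent brute-force oracles for the rank metrics. These deliberately
# enumerate pairs / thresholds rather than reusing any fast implementation.

auroc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) {
    for (b in ctrls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(ctrls))
}

auprc_oracle <- function(scores, labels) {
  # explicit threshold scan over distinct scores, descending
  th <- sort(unique(scores), decreasing = TRUE)
  tp_prev <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    fp <- sum(labels[sel] == 0)
    ap <- ap + (tp - tp_prev) * tp / (tp + fp)
    tp_prev <- tp
  }
  ap / sum(labels == 1)
}

harrell_c_oracle <- function(scores, times, events) {
  n <- length(scores)
  num <- den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # i is the earlier, definite event of the pair
      comparable <- (events[i] == 1 && times[i] < times[j]) ||
        (events[i] == 1 && events[j] == 0 && times[i] == times[j])
      if (!comparable) next
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}
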