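# independent brute-force reimplementation of the node split statistic:
# Nelson-Aalen by explicit loop, score sums and exact permutation variance
# per threshold
brute_force_splits <- function(meld, time, event, min_node = 20) {
  n <- length(meld)
  a <- numeric(n)
  for (i in seq_len(n)) {
    La <- 0
    for (s in sort(unique(time[event]))) {
      if (s > time[i]) break
      La <- La + sum(event & time == s) / sum(time >= s)
    }
    a[i] <- event[i] - La
  }
  out <- NULL
  for (cth in sort(unique(meld))) {
    nl <- sum(meld <= cth)
    if (nl < min_node || n - nl < min_node) next
    T <- sum(a[meld <= cth]) - nl * mean(a)
    V <- nl * (n - nl) / (n * (n - 1)) * sum((a - mean(a))^2)
    out <- rbind(out, c(threshold = cth, statistic = T^2 / V))
  }
  as.data.frame(out)
}

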