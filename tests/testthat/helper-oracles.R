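# Independent oracles used across suites.

# brute-force BH step-up: reject all p <= p_(k*), k* = max{k: p_(k) <= kq/m}
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) * q / m)
  if (!length(ks)) return(rep(FALSE, m))
  p <= ps[max(ks)]
}

# exhaustive best 2-partition within-cluster sum of squares on
# centered+unit-normalized rows (the clustering metric's feature space)
exhaustive_two_cluster <- function(x) {
  x <- boldcaps:::normalize_frames(x)
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    memb <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    if (all(memb) || !any(memb)) next
    wss <- 0
    for (g in list(x[memb, , drop = FALSE], x[!memb, , drop = FALSE])) {
      wss <- wss + sum(sweep(g, 2, colMeans(g))^2)
    }
    best <- min(best, wss)
  }
  best
}
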