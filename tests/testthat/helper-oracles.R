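# Brute-force null distributions for the two rank tests. These oracles
# enumerate every sign assignment / group assignment directly and stay
# independent of stats::wilcox.test.

enumerate_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_null <- as.vector(signs %*% r)
  min(1, 2 * min(mean(t_null <= t_obs), mean(t_null >= t_obs)))
}

enumerate_rank_sum_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(all_v), n1)
  w_null <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs)))
}
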