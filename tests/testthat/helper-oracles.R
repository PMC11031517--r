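# brute-force two-sided signed-rank p-value: enumerate all 2^n sign
# assignments of the rank vector one by one and count W+ at least as
# extreme as observed (independent of the package's vectorized path)
brute_force_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_obs <- min(w_plus, sum(r[d < 0]))
  total <- 2^n
  count <- 0
  for (mask in 0:(total - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    wp <- sum(r[signs])
    if (wp <= w_obs + 1e-9) count <- count + 1
  }
  min(1, 2 * count / total)
}
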