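# Independent brute-force oracles used across the test files.

# Windowed weighted std around sample i, truncated at the boundaries,
# computed by direct looping (no convolution).
brute_sliding_std <- function(x, w) {
  L <- length(w)
  h <- L %/% 2L
  sapply(seq_along(x), function(i) {
    idx <- (i - h):(i - h + L - 1L)
    keep <- idx >= 1L & idx <= length(x)
    xi <- x[idx[keep]]
    wi <- w[keep]
    m <- sum(wi * xi) / sum(wi)
    sqrt(sum(wi * (xi - m)^2) / sum(wi))
  })
}

hann_w <- function(L) 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))

# Three-loop DFA-1 reference: integrate, split into epochs, detrend each
# epoch with lm(), accumulate squared residuals.
naive_dfa_rms <- function(x, scales) {
  y <- cumsum(x - mean(x))
  N <- length(y)
  sapply(scales, function(s) {
    m <- N %/% s
    tot <- 0
    for (e in seq_len(m)) {
      idx <- ((e - 1L) * s + 1L):(e * s)
      fit <- stats::lm(y[idx] ~ idx)
      tot <- tot + sum(stats::resid(fit)^2)
    }
    sqrt(tot / (m * s))
  })
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
perm_mw_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(length(pooled), n_a)
  us <- apply(combs, 2L, function(ix) sum(rk[ix]) - n_a * (n_a + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exhaustive Youden-J maximization over midpoint candidates.
brute_youden_threshold <- function(e, o) {
  pooled <- sort(unique(c(e, o)))
  cand <- (pooled[-1] + pooled[-length(pooled)]) / 2
  j <- sapply(cand, function(th) mean(o > th) - mean(e > th))
  cand[which.max(j)]
}
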