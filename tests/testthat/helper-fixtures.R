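# shared fixtures, all built in code

# minimal four-point Mito-Stress trace at given phase levels
mito_trace <- function(levels, cycles = 1L) {
  phases <- c("baseline", "oligo", "fccp", "rotAA")
  data.frame(
    time_min = seq_len(4L * cycles) * 6.5,
    ocr = rep(levels, each = cycles),
    phase = rep(phases, each = cycles),
    stringsAsFactors = FALSE
  )
}

# exhaustive three-set Venn region counts by membership-pattern enumeration
venn_oracle <- function(a, b, c) {
  u <- unique(c(a, b, c))
  pat <- paste0(
    as.integer(u %in% a), as.integer(u %in% b), as.integer(u %in% c)
  )
  counts <- table(factor(pat, levels = c(
    "100", "010", "001", "110", "101", "011", "111"
  )))
  as.integer(counts)
}

# exhaustive hypergeometric upper tail: P(intersection >= k) when q genes are
# drawn from a domain of size N containing a term of size m
hyper_oracle <- function(k, m, N, q) {
  j <- k:min(m, q)
  sum(choose(m, j) * choose(N - m, q - j)) / choose(N, q)
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
permutation_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  p <- if (w_obs > mu) {
    2 * mean(ws >= w_obs)
  } else if (w_obs < mu) {
    2 * mean(ws <= w_obs)
  } else {
    1
  }
  list(statistic = w_obs, p = min(1, p))
}
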