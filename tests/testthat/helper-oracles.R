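# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Iteratively refined grid minimizer of sum((ln(r+1) - k t)^2), finished by
# a parabolic-vertex step on the final grid (the SSE is exactly quadratic in
# k, and plain grid refinement stalls at ~sqrt(eps) once SSE differences
# drop below double precision).
oracle_k_grid <- function(times, ratios) {
  y <- log1p(ratios)
  sse <- function(k) vapply(k, function(kk) sum((y - kk * times)^2), numeric(1))
  lo <- 0
  hi <- max(y / times) + 1e-9
  if (hi <= lo) return(0)
  for (iter in 1:2) {
    ks <- seq(lo, hi, length.out = 2001)
    vals <- sse(ks)
    i <- min(max(which.min(vals), 2L), length(ks) - 1L)
    lo <- ks[i - 1L]
    hi <- ks[i + 1L]
  }
  h <- ks[2] - ks[1]
  denom <- vals[i + 1L] - 2 * vals[i] + vals[i - 1L]
  if (denom <= 0) return(ks[i])
  ks[i] - h / 2 * (vals[i + 1L] - vals[i - 1L]) / denom
}

# Two-sided Fisher p by direct enumeration with choose() (no dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
  p_obs <- pr[xs == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Brute-force Lys-C digest: every substring bounded by cleavage sites with
# at most max_missed internal lysines, restricted to the length window.
oracle_digest_observable <- function(s, max_missed, min_len = 7, max_len = 30) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  peps <- character(0)
  for (i in seq_len(n)) {
    if (i > 1 && ch[i - 1] != "K") next
    for (j in i:n) {
      if (j < n && ch[j] != "K") next
      internal <- if (j > i) sum(ch[i:(j - 1)] == "K") else 0L
      if (internal > max_missed) next
      len <- j - i + 1
      if (len >= min_len && len <= max_len) peps <- c(peps, substr(s, i, j))
    }
  }
  unique(peps)
}

# Grid maximizer of the conditional binomial label-state likelihood
# (HH ~ p/(2-p), HL ~ 2(1-p)/(2-p)).
oracle_pool_purity <- function(hh, hl) {
  ps <- seq(1e-6, 1 - 1e-6, length.out = 200001)
  ll <- hh * log(ps / (2 - ps)) + hl * log(2 * (1 - ps) / (2 - ps))
  ps[which.max(ll)]
}

random_aa_seq <- function(n) {
  paste(sample(c(strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]], rep("K", 4)),
               n, replace = TRUE), collapse = "")
}
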