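# Brute-force oracles, independent of the package implementations.

# All permutations of 1..k as a list (recursive, distinct code path from
# the package internals).
perms_list <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perms_list(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}

# Friedman chi-square recomputed from first principles (mid-ranks plus the
# classical tie-correction divisor).
oracle_friedman_stat <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  raw <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  Tsum <- sum(apply(mat, 1, function(r) {
    tt <- as.vector(table(r)); sum(tt^3 - tt)
  }))
  C <- 1 - Tsum / (n * (k^3 - k))
  if (C <= 0) 0 else raw / C
}

# Exact permutation p by direct enumeration over (k!)^n column orders.
oracle_friedman_exact_p <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  ps <- perms_list(k)
  obs <- oracle_friedman_stat(mat)
  grid <- do.call(expand.grid, rep(list(seq_along(ps)), n))
  hits <- 0
  for (g in seq_len(nrow(grid))) {
    pm <- mat
    for (b in seq_len(n)) pm[b, ] <- mat[b, ps[[grid[g, b][[1]]]]]
    if (oracle_friedman_stat(pm) >= obs - 1e-12) hits <- hits + 1
  }
  hits / nrow(grid)
}

# Exact two-sided signed-rank p by enumerating sign patterns with bit
# arithmetic over the observed tied ranks.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    w_all[mask + 1] <- sum(r[bits])
  }
  lo <- mean(w_all <= w_obs + 1e-12)
  hi <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# Exact conditional KS tail by enumerating every split of the pooled
# sample with combn.
oracle_ks <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  grid_vals <- sort(unique(pooled))
  d_of <- function(aa, bb) {
    max(abs(stats::ecdf(aa)(grid_vals) - stats::ecdf(bb)(grid_vals)))
  }
  d_obs <- d_of(a, b)
  combos <- utils::combn(m + n, m)
  ds <- apply(combos, 2, function(idx) d_of(pooled[idx], pooled[-idx]))
  list(D = d_obs, p = mean(ds >= d_obs - 1e-12))
}
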