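new_test_result <- function(statistic, p_value, n, method, df = NA_real_,
                            z = NA_real_, tie_correction_applied = FALSE,
                            degenerate = FALSE) {
  structure(
    list(statistic = statistic, p_value = p_value, n = n, df = df, z = z,
         method = method, tie_correction_applied = tie_correction_applied,
         degenerate = degenerate),
    class = "drive_test"
  )
}

#' @export
print.drive_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic = ", signif(x$statistic, 5), sep = "")
  if (!is.na(x$df)) cat(", df = ", x$df, sep = "")
  if (!is.na(x$z)) cat(", Z = ", signif(x$z, 4), sep = "")
  cat(", n = ", x$n, ", p = ", signif(x$p_value, 4), "\n", sep = "")
  if (x$degenerate) cat("  (degenerate: no variation in the data)\n")
  invisible(x)
}

# Mid-rank based Friedman chi-square with tie correction.
friedman_statistic <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  Rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(mat, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  C <- 1 - sum(ties) / (n * (k^3 - k))
  list(stat = if (C > 0) stat / C else 0,
       tie_corrected = any(ties > 0),
       all_tied = C <= 0)
}

#' Friedman rank test for related samples
#'
#' Nonparametric one-way repeated-measures analysis over `k` related
#' treatments (here: sessions) observed in `n` blocks (drivers). Ranks are
#' taken within blocks with mid-ranks for ties and the usual tie correction
#' of the chi-square statistic. The p-value comes from the chi-square law
#' with `k - 1` degrees of freedom, or from complete enumeration of all
#' `(k!)^n` equally likely within-block rank orderings when
#' `exact = TRUE` (available for `n * k <= 12`).
#'
#' @param mat Numeric matrix, blocks x treatments.
#' @param exact Use the exact permutation null distribution.
#' @return A `drive_test` result.
#' @export
friedman_test <- function(mat, exact = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2 || n < 2) stop("need >= 2 treatments and >= 2 blocks", call. = FALSE)
  if (any(!stats::complete.cases(mat))) {
    stop("block with missing values", call. = FALSE)
  }
  fs <- friedman_statistic(mat)
  if (fs$all_tied) {
    return(new_test_result(0, 1, n, "Friedman rank test", df = k - 1,
                           tie_correction_applied = TRUE, degenerate = TRUE))
  }
  if (exact) {
    if (n * k > 12) stop("exact mode limited to n * k <= 12", call. = FALSE)
    p <- friedman_exact_p(mat)
    method <- "Friedman rank test (exact permutation)"
  } else {
    p <- stats::pchisq(fs$stat, df = k - 1, lower.tail = FALSE)
    method <- "Friedman rank test"
  }
  new_test_result(fs$stat, p, n, method, df = k - 1,
                  tie_correction_applied = fs$tie_corrected)
}

# Exact permutation p: enumerate all (k!)^n assignments of within-block
# orderings, holding each block's multiset of values fixed.
friedman_exact_p <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  obs <- friedman_statistic(mat)$stat
  perms <- all_permutations(k)
  m <- nrow(perms)
  choice <- rep(1L, n)
  count <- 0L; total <- 0L
  repeat {
    pm <- mat
    for (b in seq_len(n)) pm[b, ] <- mat[b, perms[choice[b], ]]
    if (friedman_statistic(pm)$stat >= obs - 1e-12) count <- count + 1L
    total <- total + 1L
    b <- 1L
    repeat {
      choice[b] <- choice[b] + 1L
      if (choice[b] <= m) break
      choice[b] <- 1L
      b <- b + 1L
      if (b > n) break
    }
    if (b > n) break
  }
  count / total
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

#' Wilcoxon test between two sessions
#'
#' Paired (signed-rank) test on within-driver differences by default, which
#' is the form matching a within-subject session contrast; set
#' `paired = FALSE` for the independent-samples rank-sum (Mann-Whitney)
#' form. Zero differences are dropped before ranking (Wilcoxon's original
#' treatment); tied absolute differences receive mid-ranks. The p-value is
#' exact (complete enumeration of sign assignments) for up to 12 non-zero
#' differences, otherwise from the normal approximation with tie-corrected
#' variance and continuity correction. Two-sided throughout.
#'
#' @param x,y Numeric vectors of per-driver counts for the two sessions
#'   (equal length when `paired = TRUE`).
#' @param paired Use the signed-rank form (default).
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact enumeration is used.
#' @return A `drive_test` result.
#' @export
wilcoxon_paired_test <- function(x, y, paired = TRUE, exact_limit = 12) {
  if (!paired) return(rank_sum_test(x, y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_test_result(0, 1, 0, "Wilcoxon signed-rank test",
                           degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tt <- table(r)
  tie_term <- sum(tt^3 - tt) / 48
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term
  z <- if (sigma2 > 0) {
    cc <- sign(w_pos - mu) * 0.5
    (w_pos - mu - cc) / sqrt(sigma2)
  } else 0
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, w_pos)
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  new_test_result(w_pos, min(p, 1), n, method, z = z,
                  tie_correction_applied = tie_term > 0,
                  degenerate = sigma2 <= 0)
}

# Exact two-sided p by enumeration of all 2^n sign assignments of the
# observed (possibly tied) ranks: p = 2 * min tail, capped at 1.
signed_rank_exact_p <- function(r, w_obs) {
  n <- length(r)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  lo <- mean(w_all <= w_obs + 1e-12)
  hi <- mean(w_all >= w_obs - 1e-12)
  min(2 * min(lo, hi), 1)
}

# Independent-samples Wilcoxon rank-sum (Mann-Whitney) with mid-ranks,
# tie-corrected variance and continuity correction.
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  tt <- table(r)
  sigma2 <- n1 * n2 / 12 * (nn + 1 - sum(tt^3 - tt) / (nn * (nn - 1)))
  if (sigma2 <= 0) {
    return(new_test_result(u, 1, nn, "Wilcoxon rank-sum test",
                           degenerate = TRUE))
  }
  cc <- sign(u - mu) * 0.5
  z <- (u - mu - cc) / sqrt(sigma2)
  new_test_result(u, min(2 * stats::pnorm(-abs(z)), 1), nn,
                  "Wilcoxon rank-sum test (normal approximation)", z = z,
                  tie_correction_applied = any(tt > 1))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical distribution
#' functions. The p-value is exact (conditional on the pooled sample, by
#' lattice-path counting that accommodates ties) when `m * n <= 100`,
#' otherwise from the asymptotic Kolmogorov distribution.
#'
#' @param a,b Numeric samples.
#' @return A `drive_test` result.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty",
                                             call. = FALSE)
  m <- length(a); n <- length(b)
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  D <- max(abs(Fa - Fb))
  if (m * n <= 100) {
    p <- ks_exact_p(sort(a), sort(b), D)
    method <- "Two-sample Kolmogorov-Smirnov test (exact)"
  } else {
    lambda <- sqrt(m * n / (m + n)) * D
    j <- 1:100
    p <- min(max(2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2)), 0), 1)
    method <- "Two-sample Kolmogorov-Smirnov test (asymptotic)"
  }
  new_test_result(D, p, m + n, method, degenerate = D == 0)
}

# Exact conditional tail P(D >= d_obs), conditioning on the pooled sample.
# Each of the choose(m + n, m) label assignments is an equally likely
# monotone lattice path from (0, 0) to (m, n); the ECDF distance is checked
# only where the pooled value changes (and at the end), which is exactly
# how ties affect D. Counts paths whose distance stays strictly below
# d_obs at every checkpoint; the complement is the tail probability.
ks_exact_p <- function(a, b, d_obs) {
  m <- length(a); n <- length(b)
  pooled <- sort(c(a, b))
  N <- m + n
  checkpoint <- c(diff(pooled) > 0, TRUE)
  u <- rep(0, m + 1) # u[i + 1] = good paths with i a-steps after k steps
  u[1] <- 1
  for (k in seq_len(N)) {
    u_new <- rep(0, m + 1)
    for (i in 0:min(k, m)) {
      j <- k - i
      if (j > n) next
      from_a <- if (i > 0) u[i] else 0
      from_b <- if (j > 0) u[i + 1] else 0
      u_new[i + 1] <- from_a + from_b
      if (checkpoint[k] && abs(i / m - j / n) >= d_obs - 1e-12) {
        u_new[i + 1] <- 0
      }
    }
    u <- u_new
  }
  1 - sum(u) / choose(N, m)
}
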