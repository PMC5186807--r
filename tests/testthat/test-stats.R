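test_that("Friedman statistic matches the worked examples", {
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  f <- friedman_test(m)
  expect_equal(f$statistic, 8 / 3, tolerance = 1e-10) # 2.667
  expect_equal(f$df, 2)
  # perfectly concordant rankings reach the k = 3, n = 3 maximum
  conc <- rbind(c(1, 2, 3), c(4, 5, 6), c(0, 1, 2))
  expect_equal(friedman_test(conc)$statistic, 6)
  # a constant matrix is degenerate
  const <- friedman_test(matrix(5, 3, 3))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_true(const$degenerate)
})

test_that("Friedman agrees with base R on tie-free data", {
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- matrix(sample(100, 15 * 5), 15, 5)
      mine <- friedman_test(m)
      ref <- stats::friedman.test(m)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value)
    }
  })
})

test_that("exact Friedman p matches full permutation enumeration", {
  cases <- list(
    rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3)),
    rbind(c(0, 0, 2), c(1, 1, 1), c(3, 1, 0)), # ties inside blocks
    rbind(c(2, 5, 1, 4), c(3, 3, 2, 6)),       # k = 4, n = 2
    rbind(c(4, 1, 0), c(0, 2, 2), c(5, 5, 5), c(1, 0, 3)) # k = 3, n = 4
  )
  for (m in cases) {
    expect_equal(friedman_test(m, exact = TRUE)$p_value,
                 oracle_friedman_exact_p(m), tolerance = 1e-12)
    expect_equal(friedman_test(m)$statistic, oracle_friedman_stat(m))
  }
})

test_that("Friedman is invariant to block relabeling and monotone maps", {
  withr::with_seed(9, m <- matrix(rpois(24, 4), 6, 4))
  base <- friedman_test(m)
  perm <- friedman_test(m[sample(6), ])
  expect_equal(perm$statistic, base$statistic)
  expect_equal(perm$p_value, base$p_value)
  mono <- friedman_test(exp(m)) # strictly increasing transform
  expect_equal(mono$statistic, base$statistic)
})

test_that("signed-rank statistic and exact p match the worked examples", {
  w <- wilcoxon_paired_test(c(1, -2, 3, 4), rep(0, 4))
  expect_equal(w$statistic, 8) # W+ = 8, W- = 2
  expect_equal(w$p_value, oracle_signed_rank_p(c(1, -2, 3, 4)))
  # six all-positive differences: two-sided exact p = 2/64
  w6 <- wilcoxon_paired_test(1:6, rep(0, 6))
  expect_equal(w6$p_value, 2 / 64)
  # identical samples are degenerate
  eq <- wilcoxon_paired_test(1:5, 1:5)
  expect_equal(eq$p_value, 1)
  expect_true(eq$degenerate)
})

test_that("signed-rank matches enumeration oracle and base R", {
  withr::with_seed(21, {
    for (i in 1:6) {
      x <- rpois(8, 5); y <- rpois(8, 4)
      mine <- wilcoxon_paired_test(x, y)
      expect_equal(mine$p_value, oracle_signed_rank_p(x - y),
                   tolerance = 1e-12)
      d <- x - y
      if (length(unique(abs(d[d != 0]))) == sum(d != 0) && all(d != 0)) {
        ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
        expect_equal(mine$p_value, ref$p.value)
      }
    }
  })
  # large-sample path agrees with the corrected normal approximation
  withr::with_seed(22, {
    x <- rpois(20, 6); y <- rpois(20, 4)
  })
  mine <- wilcoxon_paired_test(x, y, exact_limit = 0)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the independent-samples rank-sum mode matches base R", {
  withr::with_seed(31, {
    a <- rpois(10, 5); b <- rpois(12, 7)
  })
  mine <- wilcoxon_paired_test(a, b, paired = FALSE)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("KS distance and exact p match the oracle", {
  expect_equal(ks_two_sample(1:3, 4:6)$statistic, 1)
  eq <- ks_two_sample(1:3, 1:3)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  d2 <- ks_two_sample(c(1, 2), c(1, 3))
  expect_equal(d2$statistic, 0.5)
  cases <- list(
    list(a = c(1, 2), b = c(1, 3)),
    list(a = c(0, 0, 1, 4), b = c(2, 2, 3)),
    list(a = rpois(5, 3), b = rpois(6, 5)),
    list(a = c(1.5, 2.5, 9), b = c(0.5, 2.5, 2.5, 7))
  )
  withr::with_seed(41, cases[[3]] <- list(a = rpois(5, 3), b = rpois(6, 5)))
  for (cs in cases) {
    mine <- ks_two_sample(cs$a, cs$b)
    orc <- oracle_ks(cs$a, cs$b)
    expect_equal(mine$statistic, orc$D)
    expect_equal(mine$p_value, orc$p, tolerance = 1e-12)
  }
})

test_that("KS agrees with base R for tie-free samples", {
  withr::with_seed(7, {
    a <- rnorm(8); b <- rnorm(9, 0.4)
  })
  mine <- ks_two_sample(a, b)
  ref <- stats::ks.test(a, b, exact = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # asymptotic branch
  withr::with_seed(8, {
    a2 <- rnorm(30); b2 <- rnorm(25, 0.3)
  })
  mine2 <- ks_two_sample(a2, b2)
  ref2 <- stats::ks.test(a2, b2, exact = FALSE)
  expect_equal(mine2$statistic, unname(ref2$statistic))
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-6)
})

test_that("p-values are invariant under driver relabeling", {
  withr::with_seed(13, {
    x <- rpois(10, 6); y <- rpois(10, 3)
  })
  base <- wilcoxon_paired_test(x, y)
  idx <- sample(10)
  perm <- wilcoxon_paired_test(x[idx], y[idx])
  expect_equal(perm$statistic, base$statistic)
  expect_equal(perm$p_value, base$p_value)
})
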