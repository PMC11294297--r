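test_that("Bland-Altman handles identical pairs and the worked example", {
  ba0 <- bland_altman(c(3, 5, 9), c(3, 5, 9))
  expect_identical(ba0$bias_pct, 0)
  expect_identical(ba0$sd_pct, 0)
  expect_identical(ba0$loa_low_pct, 0)
  # hand-computed: diffs 100*10/105, -100*10/95, 0
  ba <- bland_altman(c(110, 90, 100), c(100, 100, 100))
  d <- c(1000 / 105, -1000 / 95, 0)
  expect_equal(ba$diff_pct, d, tolerance = 1e-12)
  expect_equal(ba$bias_pct, mean(d), tolerance = 1e-12)
  expect_equal(ba$bias_pct, -0.33417, tolerance = 1e-4)
  expect_equal(ba$sd_pct, 10.02922, tolerance = 1e-4)
  expect_equal(ba$loa_high_pct, ba$bias_pct + 1.96 * ba$sd_pct)
  expect_equal(ba$loa_low_pct, ba$bias_pct - 1.96 * ba$sd_pct)
})

test_that("Bland-Altman is antisymmetric and scale-free in pair-mean mode", {
  set.seed(6)
  x <- runif(10, 50, 150); y <- runif(10, 50, 150)
  f <- bland_altman(x, y)
  r <- bland_altman(y, x)
  expect_equal(r$diff_pct, -f$diff_pct, tolerance = 1e-12)
  expect_equal(r$bias_pct, -f$bias_pct, tolerance = 1e-12)
  s <- bland_altman(7.3 * x, 7.3 * y)
  expect_equal(s$bias_pct, f$bias_pct, tolerance = 1e-12)
  expect_equal(s$sd_pct, f$sd_pct, tolerance = 1e-12)
})

test_that("Bland-Altman reference mode recovers a known ratio and validates", {
  ref <- c(100, 150, 200)
  ba <- bland_altman(1.1007 * ref, ref, denominator_mode = "reference")
  expect_equal(ba$bias_pct, 10.07, tolerance = 1e-10)
  expect_equal(ba$sd_pct, 0, tolerance = 1e-10)
  expect_error(bland_altman(1, 1), "2 pairs")
  expect_error(bland_altman(c(1, 2), c(0, 1)), "positive")
})

test_that("the signed-rank example and degenerate input behave per contract", {
  w <- wilcoxon_paired(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_identical(w$statistic, 15)
  expect_identical(w$p_value, 2 / 32)
  expect_identical(w$method, "exact")
  expect_error(wilcoxon_paired(c(1, 2, 3), c(1, 2, 3)), "degenerate")
})

test_that("exact signed-rank p matches brute-force enumeration up to n = 12", {
  set.seed(8)
  for (n in c(2, 3, 5, 8, 10, 12)) {
    for (rep in 1:3) {
      x <- round(rnorm(n, 0, 2), 1)
      y <- round(rnorm(n, 0, 2), 1)
      if (all(x == y)) x[1] <- x[1] + 1
      got <- wilcoxon_paired(x, y)
      expect_identical(got$method, "exact")
      expect_equal(got$p_value, bruteforce_signed_rank_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact enumeration agrees with stats::wilcox.test on tie-free data", {
  set.seed(13)
  for (rep in 1:5) {
    x <- rnorm(10); y <- rnorm(10)  # continuous: no ties, no zeros
    got <- wilcoxon_paired(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p at the cohort size", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(18); y <- rnorm(18)
    pe <- wilcoxon_paired(x, y, exact_max = 18L)
    pn <- wilcoxon_paired(x, y, exact_max = 0L)
    expect_identical(pe$method, "exact")
    expect_identical(pn$method, "normal_approx")
    expect_lt(abs(pe$p_value - pn$p_value), 0.02)
  }
})
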