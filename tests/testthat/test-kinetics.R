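test_that("the tri-exponential model is anchored at zero and decays", {
  p <- triexp_params(2, 1, 0.01, 0.05, 0.5)
  expect_identical(triexp_value(p, 0), 0)
  expect_equal(triexp_value(p, 24),
               2 * exp(-0.24) + exp(-1.2) - 3 * exp(-12), tolerance = 1e-12)
  expect_lt(abs(triexp_value(p, 1e6)), 1e-12 * 3)
  set.seed(2)
  for (i in 1:20) {
    q <- sample_valid_params()
    expect_identical(triexp_value(q, 0), 0)
  }
})

test_that("closed-form TIAC matches its algebra and rejects bad rates", {
  expect_equal(tiac_closed_form(triexp_params(0, 0, 1, 1, 1)), 0)
  p <- triexp_params(2, 1, 0.01, 0.05, 0.5)
  expect_equal(tiac_closed_form(p), 2 / 0.01 + 1 / 0.05 - 3 / 0.5)
  # A2 = 0 reduces to A1 (1/b - 1/d)
  q <- triexp_params(3, 0, 0.02, 0.05, 0.4)
  expect_equal(tiac_closed_form(q), 3 * (1 / 0.02 - 1 / 0.4))
  expect_error(tiac_closed_form(triexp_params(1, 1, 0, 0.05, 0.5)),
               "divergent")
})

test_that("numeric quadrature TIAC agrees with the closed form", {
  p <- triexp_params(2, 1, 0.01, 0.05, 0.5)
  expect_equal(tiac_numeric(p, 1e-10), 214, tolerance = 214 * 1e-8)
  expect_identical(tiac_numeric(triexp_params(0, 0, 1, 1, 1)), 0)
  set.seed(4)
  for (i in 1:200) {
    q <- sample_valid_params()
    cf <- tiac_closed_form(q)
    expect_equal(tiac_numeric(q, 1e-8), cf,
                 tolerance = max(abs(cf), 1) * 1e-8)
  }
})

test_that("time-activity series enforce the administration zero anchor", {
  s <- ta_series(c(4, 24, 48, 168), c(5, 4, 3, 1))
  expect_true(s$includes_zero_anchor)
  expect_identical(s$time_h[1], 0)
  expect_identical(s$conc_Bq_mL[1], 0)
  s2 <- ta_series(c(0, 4, 24, 48, 168), c(0, 5, 4, 3, 1))
  expect_identical(s2$time_h, s$time_h)
  expect_error(ta_series(c(0, 4), c(1, 5)), "anchor")
  expect_error(ta_series(c(4, 4, 24, 48), c(1, 1, 1, 1)), "increasing")
  expect_error(ta_series(c(4, 24), c(-1, 1)), ">= 0")
})

test_that("series CSV round-trips per organ", {
  series <- list(kidney_L = ta_series(c(4, 24, 48, 168), c(5, 4, 3, 1)),
                 spleen = ta_series(c(4, 24, 48, 168), c(2, 2, 1, 0.5)))
  path <- tempfile(fileext = ".csv")
  write_series_csv(series, path)
  back <- read_series_csv(path)
  expect_setequal(names(back), names(series))
  expect_equal(back$kidney_L$conc_Bq_mL, series$kidney_L$conc_Bq_mL)
  expect_equal(back$spleen$time_h, series$spleen$time_h)
})

test_that("noise-free fits recover TIAC conservatively and accurately", {
  set.seed(42)
  errs <- numeric(30)
  for (i in 1:30) {
    p <- sample_truth_params()
    y <- triexp_value(p, c(4, 24, 48, 168))
    f <- suppressWarnings(fit_triexp(ta_series(c(4, 24, 48, 168), y)))
    expect_true(f$converged)
    # the fitted curve interpolates the data and passes through (0, 0)
    expect_identical(triexp_value(f$params, 0), 0)
    expect_lt(f$sse, (1e-8 * max(y))^2 * 8)
    errs[i] <- (f$tiac - tiac_closed_form(p)) / tiac_closed_form(p)
  }
  # minimum-TIAC selection: never far above truth, within 1% overall,
  # typically much closer
  expect_lt(max(errs), 1e-4)
  expect_lt(max(abs(errs)), 0.01)
  expect_lt(abs(stats::median(errs)), 1e-3)
})

test_that("the 214-TIAC example is recovered at the nominal times", {
  p <- triexp_params(2, 1, 0.01, 0.05, 0.5)
  y <- triexp_value(p, c(4, 24, 48, 168))
  f <- fit_triexp(ta_series(c(4, 24, 48, 168), y))
  expect_equal(f$tiac, 214, tolerance = 0.2 / 214)
})

test_that("fitting is equivariant under concentration rescaling", {
  set.seed(9)
  p <- sample_truth_params()
  y <- triexp_value(p, c(4, 24, 48, 168))
  f1 <- fit_triexp(ta_series(c(4, 24, 48, 168), y))
  for (alpha in c(1e-3, 17, 3e5)) {
    f2 <- fit_triexp(ta_series(c(4, 24, 48, 168), alpha * y))
    expect_equal(f2$tiac, alpha * f1$tiac, tolerance = 1e-3)
  }
})

test_that("degenerate and invalid series are handled per contract", {
  f0 <- fit_triexp(ta_series(c(4, 24, 48, 168), c(0, 0, 0, 0)))
  expect_identical(f0$tiac, 0)
  expect_identical(f0$sse, 0)
  expect_error(fit_triexp(ta_series(c(4, 24, 48), c(1, 2, 1))), "4 positive")
})

test_that("fit results serialise to JSON and back", {
  p <- triexp_params(2, 1, 0.01, 0.05, 0.5)
  y <- triexp_value(p, c(4, 24, 48, 168))
  f <- fit_triexp(ta_series(c(4, 24, 48, 168), y))
  path <- tempfile(fileext = ".json")
  fit_to_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$tiac, f$tiac)
  expect_equal(back$params$b, f$params$b)
  expect_true(back$converged)
})
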