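test_that("fit_ogive matches the brute-force likelihood oracle", {
  sets <- list(
    small_maturity_data(),
    data.frame(length = c(16, 18, 19, 20, 21, 22, 23, 25),
               mature = c(0, 1, 0, 0, 1, 0, 1, 1)),
    data.frame(length = c(10, 12, 14, 15, 16, 18, 20, 21, 22, 24),
               mature = c(0, 0, 1, 0, 1, 0, 1, 1, 0, 1))
  )
  for (d in sets) {
    fit <- fit_ogive(d)
    oracle <- grid_logit_oracle(d$length, d$mature)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-4)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-4)
    expect_equal(fit$loglik_full, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("symmetric data give L50 at the centre", {
  len <- c(16, 17, 18, 19, 21, 22, 23, 24)
  mat <- c(0, 1, 0, 0, 1, 1, 0, 1)   # outcomes mirror-symmetric about 20
  fit <- fit_ogive(len, mat)
  expect_equal(fit$L50, 20, tolerance = 1e-6)
})

test_that("nagelkerke matches its closed form and limits", {
  expect_equal(nagelkerke(-10, -10, 20), 0)
  expect_equal(nagelkerke(-10, 0, 20), 1)
  ll0 <- -104.3; ll1 <- -55.1; n <- 151
  cox <- 1 - exp(2 * (ll0 - ll1) / n)
  expect_equal(nagelkerke(ll0, ll1, n), cox / (1 - exp(2 * ll0 / n)),
               tolerance = 1e-10)
  expect_error(nagelkerke(-10, -20, 5), ">=")
  expect_error(nagelkerke(-10, -5, 0), "n must be")
  # agrees with the fit's own bookkeeping
  d <- small_maturity_data()
  fit <- fit_ogive(d)
  expect_equal(fit$nagelkerke_r2,
               nagelkerke(fit$loglik_null, fit$loglik_full, fit$n),
               tolerance = 1e-12)
})

test_that("ogive_curve: exact half at L50, monotone, correct limits", {
  fit <- fit_ogive(small_maturity_data())
  expect_identical(ogive_curve(fit, fit$L50), 0.5)
  xs <- seq(5, 40, by = 0.5)
  expect_true(all(diff(ogive_curve(fit, xs)) >= 0))
  expect_equal(ogive_curve(fit, -1e6), 0)
  expect_equal(ogive_curve(fit, 1e6), 1)
})

test_that("L50 shifts by exactly c when lengths shift by c", {
  d <- small_maturity_data()
  f0 <- fit_ogive(d$length, d$mature)
  f5 <- fit_ogive(d$length + 5, d$mature)
  expect_equal(f5$L50, f0$L50 + 5, tolerance = 1e-6)
  expect_equal(f5$slope, f0$slope, tolerance = 1e-6)
})

test_that("degenerate and separated data are handled", {
  expect_error(fit_ogive(c(10, 20), c(1, 1)), "same maturity outcome")
  expect_error(fit_ogive(20, 1), "at least 2")
  len <- c(15, 16, 17, 21, 22, 23)
  mat <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_ogive(len, mat), "separation")
  expect_false(fit$converged)
  expect_equal(fit$L50, 19)        # midpoint of the (17, 21) gap
  expect_error(ogive_curve(fit, 20), "converge")
})

test_that("class midpoints snap lengths to 1-cm class centres", {
  len <- c(15.2, 15.9, 18.4, 20.7, 22.1, 23.8)
  mat <- c(0, 0, 0, 1, 1, 1)
  f <- suppressWarnings(fit_ogive(len, mat, class_midpoints = TRUE))
  expect_equal(f$L50, (18.5 + 20.5) / 2)   # separation midpoint on midpoints
})

test_that("bootstrap_L50: reproducible, ordered CI, audit trail", {
  set.seed(31)
  len <- runif(80, 14, 30)
  mat <- runif(80) < plogis(1.2 * (len - 21))
  b1 <- bootstrap_L50(len, mat, reps = 200, seed = 5)
  b2 <- bootstrap_L50(len, mat, reps = 200, seed = 5)
  expect_identical(b1$values, b2$values)
  expect_lte(b1$ci_low, b1$L50_median)
  expect_lte(b1$L50_median, b1$ci_high)
  expect_equal(length(b1$values), 200)
  expect_false(b1$warning)
  expect_error(bootstrap_L50(len, mat, reps = 10), "seed")
})

test_that("near-degenerate bootstrap collapses to a narrow interval", {
  # two tight length clusters: every resample with both outcomes present
  # separates at the same gap, so converged replicates are rare and the
  # retained L50s (if any) pile up; the common case is an informative error
  len <- c(rep(15, 6), rep(25, 6))
  mat <- c(rep(0, 6), rep(1, 6))
  res <- tryCatch(
    suppressWarnings(bootstrap_L50(len, mat, reps = 50, seed = 2)),
    error = function(e) e)
  expect_true(inherits(res, "error") || res$ci_high - res$ci_low < 1e-6)
})
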