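test_that("noise-free Stern-Volmer data refit exactly", {
  fit <- fit_stern_volmer(sv_series(ksv = 1.07e4))
  expect_lt(abs(fit$ksv - 1.07e4) / 1.07e4, 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_identical(fit$kq, fit$ksv / fit$tau0)
  expect_equal(fit$kq, 1.07e12)
})

test_that("degenerate and invalid inputs are refused", {
  q <- seq(0, 1e-4, 2e-5)
  flat <- titration_series(q, rep(500, length(q)), temperature = 303)
  expect_equal(fit_stern_volmer(flat)$ksv, 0)

  expect_error(fit_stern_volmer(titration_series(c(0, 1e-5), c(100, 90),
                                                 temperature = 303)),
               "insufficient titration")
  zero <- titration_series(c(0, 1e-5, 2e-5), c(100, 50, 0), temperature = 303)
  expect_error(fit_stern_volmer(zero), "zero intensity")
})

test_that("OLS slope agrees with closed-form oracles", {
  # exact line through (0,1): slope (1.5 - 1)/5e-5 = 1e4
  s <- titration_series(c(0, 2.5e-5, 5e-5), c(600, 480, 400), temperature = 303)
  fit <- fit_stern_volmer(s)
  expect_equal(fit$ksv, 1e4, tolerance = 1e-10)

  # closed-form covariance/variance slope on noisy data
  set.seed(42)
  for (i in 1:10) {
    q <- seq(0, 1e-4, length.out = 8)
    f0 <- 800
    f <- f0 / (1 + 9e3 * q) * (1 + rnorm(8, 0, 0.01))
    f[q == 0] <- f0
    ss <- titration_series(q, f, temperature = 303)
    fit <- suppressWarnings(fit_stern_volmer(ss))
    expect_equal(fit$ksv, ols_slope(q, f0 / f), tolerance = 1e-9)
  }
})

test_that("fixed-intercept mode pins the line at (0, 1)", {
  s <- sv_series(ksv = 5e3)
  fit <- fit_stern_volmer(s, fix_intercept = TRUE)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$ksv, 5e3, tolerance = 1e-8)
})

test_that("K_SV estimates converge to truth as noise shrinks", {
  ksv <- 1.07e4
  mean_err <- vapply(c(0.02, 0.01, 0.005), function(sig) {
    errs <- vapply(1:40, function(i) {
      b <- generate_titration(synthetic_config(ksv = ksv, noise_rel_sigma = sig,
                                               temperatures = 303,
                                               seed = 1000 + i))
      fit <- suppressWarnings(fit_stern_volmer(b$series_by_T[[1]]))
      abs(fit$ksv - ksv) / ksv
    }, 0)
    mean(errs)
  }, 0)
  expect_true(all(diff(mean_err) < 0))
  expect_lt(mean_err[3], 0.02)
})

test_that("mechanism classification follows the temperature-trend rule set", {
  mk <- function(ksv, temp, tau0 = 1e-8) {
    fit_stern_volmer(sv_series(ksv = ksv, temperature = temp), tau0 = tau0)
  }
  # decreasing ladder, all kq over the diffusion limit -> static
  fits <- list(mk(1.07e4, 303), mk(0.82e4, 310), mk(0.48e4, 318))
  call <- classify_mechanism(fits)
  expect_equal(call$mechanism, "static")
  expect_equal(call$ksv_trend, "decreasing")
  expect_true(call$kq_exceeds_limit)

  # order of supply is irrelevant
  expect_equal(classify_mechanism(fits[c(3, 1, 2)])$mechanism, "static")

  # increasing ladder with kq within the limit -> dynamic
  dyn <- list(mk(0.5e4, 303, tau0 = 1e-5), mk(0.8e4, 310, tau0 = 1e-5),
              mk(1.1e4, 318, tau0 = 1e-5))
  expect_equal(classify_mechanism(dyn)$mechanism, "dynamic")

  # increasing ladder with kq above the limit -> mixed
  mixed <- list(mk(0.5e4, 303), mk(0.8e4, 310), mk(1.1e4, 318))
  expect_equal(classify_mechanism(mixed)$mechanism, "mixed")

  # non-monotonic -> indeterminate
  nm <- list(mk(1e4, 303), mk(0.5e4, 310), mk(0.8e4, 318))
  expect_equal(classify_mechanism(nm)$mechanism, "indeterminate")

  # single temperature classifies on kq alone
  single <- classify_mechanism(mk(1.07e4, 303))
  expect_equal(single$mechanism, "static")
  expect_equal(single$ksv_trend, "single-T")
  expect_equal(classify_mechanism(mk(1e4, 303, tau0 = 1e-5))$mechanism,
               "indeterminate")

  expect_error(classify_mechanism(list(mk(1e4, 303), mk(2e4, 303))),
               "invalid temperature ladder")
})

test_that("kq/ksv ratio is exactly 1/tau0 across random fits", {
  set.seed(7)
  for (i in 1:10) {
    tau0 <- 10^runif(1, -9, -5)
    fit <- fit_stern_volmer(sv_series(ksv = 10^runif(1, 3, 5)), tau0 = tau0)
    expect_identical(fit$kq, fit$ksv / tau0)
  }
})
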