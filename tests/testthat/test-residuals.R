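test_that("censored Weibull fit recovers generating parameters", {
  withr::with_seed(31, {
    te <- rweibull(2000, 2, 15)
    to <- sim_observation_age(2000)
    ev <- as.integer(te < to)
    tt <- ifelse(ev == 1, te, to)
    fit <- fit_weibull_censored(tt, ev)
    expect_lt(abs(fit$shape - 2) / 2, 0.05)
    expect_lt(abs(fit$scale - 15) / 15, 0.05)
    expect_identical(fit$n_events + fit$n_censored, 2000L)
    expect_s3_class(tidy(fit), "tbl_df")
    expect_identical(glance(fit)$nobs, 2000L)
  })
  expect_error(fit_weibull_censored(c(1, 2, 3), c(0, 0, 0)), "2 events")
  expect_error(fit_weibull_censored(c(0, 2, 3), c(1, 1, 1)), "positive")
})

test_that("parameter recovery is accurate at cohort scale", {
  # ~40% censoring, n = 400, as in the simulated cohorts
  errs <- vapply(1:50, function(r) {
    withr::with_seed(1000 + r, {
      te <- rweibull(400, 3.8, 14.5)
      to <- sim_observation_age(400)
      ev <- as.integer(te < to)
      fit <- fit_weibull_censored(ifelse(ev == 1, te, to), ev)
      max(abs(fit$shape - 3.8) / 3.8, abs(fit$scale - 14.5) / 14.5)
    })
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("weibull mean matches the closed form and the survival integral", {
  expect_equal(weibull_mean(1, 15), 15)
  expect_equal(weibull_mean(2, 1), gamma(1.5))
  fit <- structure(list(shape = 2.3, scale = 12), class = "weibull_fit")
  num <- integrate(function(t) exp(-(t / 12)^2.3), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(weibull_mean(fit), num, tolerance = 1e-6)
})

test_that("conditional mean beyond a censoring time matches quadrature", {
  # unconditional limit at c = 0
  expect_equal(conditional_mean_beyond(2, 0, scale = 15), weibull_mean(2, 15))
  # exponential memorylessness: E[T | T > c] = c + mean
  expect_equal(conditional_mean_beyond(1, 10, scale = 15), 25, tolerance = 1e-9)
  # quadrature oracle
  expect_equal(conditional_mean_beyond(2, 20, scale = 15),
               quad_conditional_mean(2, 15, 20), tolerance = 1e-6)
  expect_equal(conditional_mean_beyond(3.5, 17, scale = 13),
               quad_conditional_mean(3.5, 13, 17), tolerance = 1e-6)
  # nondecreasing in c, always >= c, saturates when S(c) underflows
  cs <- seq(0, 60, by = 0.5)
  v <- conditional_mean_beyond(2, cs, scale = 15)
  expect_true(all(diff(v) >= -1e-9))
  expect_true(all(v >= cs))
  expect_equal(conditional_mean_beyond(2, 1e6, scale = 15), 1e6)
  expect_error(conditional_mean_beyond(2, -1, scale = 15), ">= 0")
})

test_that("uncensored residuals are exact deviations from the stratum mean", {
  coh <- tiny_cohort(300, seed = 41)
  coh$event <- 1L  # treat everything as observed
  res <- ote_residuals(coh, standardize = FALSE)
  fits <- attr(res, "weibull_fits")
  for (y in c("1", "2")) {
    sel <- coh$covariate == as.integer(y)
    expect_equal(res$residual[sel], coh$time[sel] - weibull_mean(fits[[y]]))
  }
})

test_that("censored residuals exceed the censoring-time deviation", {
  coh <- tiny_cohort(400, seed = 42)
  res <- ote_residuals(coh, standardize = FALSE)
  fits <- attr(res, "weibull_fits")
  cens <- coh$event == 0
  for (y in 1:2) {
    sel <- cens & coh$covariate == y
    mu <- weibull_mean(fits[[as.character(y)]])
    expect_true(all(res$residual[sel] > coh$time[sel] - mu))
  }
})

test_that("null-model residual means are centered within sampling error", {
  vals <- vapply(1:40, function(r) {
    coh <- sim_cohort(generating_model("M1"), 400,
                      seed = replicate_seed(43, r))
    res <- ote_residuals(coh, standardize = FALSE)
    tapply(res$residual, coh$covariate, mean)
  }, numeric(2))
  for (y in 1:2) {
    m <- mean(vals[y, ])
    se <- sd(vals[y, ]) / sqrt(ncol(vals))
    expect_lt(abs(m), 3 * se + 0.05)
  }
})

test_that("standardization yields mean 0, sd 1 and is idempotent", {
  coh <- tiny_cohort(200, seed = 44)
  res <- ote_residuals(coh)
  expect_lt(abs(mean(res$residual)), 1e-8)
  expect_lt(abs(sd(res$residual) - 1), 1e-8)
  expect_true(attr(res, "standardized"))
  again <- standardize_residuals(res)
  expect_equal(again$residual, res$residual, tolerance = 1e-12)
  const <- tibble::tibble(residual = rep(1, 10))
  expect_error(standardize_residuals(const), "variance")
})

test_that("unstratified residuals use one pooled fit", {
  coh <- tiny_cohort(200, seed = 45)
  res <- ote_residuals(coh, stratify = FALSE, standardize = FALSE)
  fits <- attr(res, "weibull_fits")
  expect_named(fits, "all")
  ev <- coh$event == 1
  expect_equal(res$residual[ev], coh$time[ev] - weibull_mean(fits$all))
})
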