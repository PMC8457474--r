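test_that("genotypes follow Hardy-Weinberg proportions", {
  withr::with_seed(1, {
    expect_true(all(sim_genotypes(100, 0) == 0))
    for (maf in c(0.1, 0.3, 0.5)) {
      g <- sim_genotypes(1e6, maf)
      exp_p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
      for (k in 0:2) {
        se <- sqrt(exp_p[k + 1] * (1 - exp_p[k + 1]) / 1e6)
        expect_lt(abs(mean(g == k) - exp_p[k + 1]), 3 * se)
      }
    }
  })
  expect_error(sim_genotypes(10, 0.6), "maf")
  expect_error(sim_genotypes(10, -0.1), "maf")
})

test_that("zero minor-homozygote replicates match the binomial zero class", {
  # P(no genotype-2 individual among 400 at MAF 0.1) = (1 - 0.01)^400
  withr::with_seed(2, {
    n_rep <- 3000
    zero <- replicate(n_rep, !any(sim_genotypes(400, 0.1) == 2L))
    p0 <- (1 - 0.01)^400
    expect_lt(abs(mean(zero) - p0), 3 * sqrt(p0 * (1 - p0) / n_rep))
  })
})

test_that("covariate assignment follows the fixed and random laws", {
  y <- sim_covariates(400, "fixed")
  expect_identical(sum(y == 1L), 200L)
  expect_identical(sum(y == 2L), 200L)
  y5 <- sim_covariates(5, "fixed")
  expect_identical(sum(y5 == 1L), 2L)
  withr::with_seed(3, {
    expect_true(sim_covariates(1, "random") %in% 1:2)
    fr <- replicate(400, mean(sim_covariates(50, "random") == 2L))
    # var of a replicate fraction = alpha-variation + binomial noise
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - 0.7), 3 * se + 0.005)
    alphas <- replicate(2000, attr(sim_covariates(2, "random"), "alpha"))
    expect_true(all(alphas > 0 & alphas < 1))
  })
})

test_that("observation ages are positive with NB(10, 0.4) moments", {
  withr::with_seed(4, {
    a <- sim_observation_age(1e6)
    expect_true(all(a > 0))
    expect_lt(abs(mean(a) - 15), 3 * sqrt(37.5 / 1e6) + 0.002)
    expect_lt(abs(var(a) - 37.5), 0.5)
  })
})

test_that("cell distributions map the standard scale to years", {
  m1 <- generating_model("M1")
  c11 <- cell_distribution(m1, 0, 1)
  expect_equal(unname(c11$params), c(11.6, 3.4))
  m2 <- generating_model("M2")
  expect_equal(cell_distribution(m2, 2, 2)$mean, 11.6 + 3.4 * 0.5 + 3)
  # Model 8 has explicit y = 2 cells and no extra offset
  m8 <- generating_model("M8")
  c8 <- cell_distribution(m8, 0, 2)
  expect_equal(c8$mean, 11.6 + 3.4 * 1.26)
  expect_equal(c8$sd, 3.4 * 2)
  # Epi models add the 3-year offset to their y = 2 cells
  e1 <- generating_model("Epi1")
  expect_equal(cell_distribution(e1, 2, 2)$mean, 11.6 + 3.4 * 0.5 + 3)
  expect_equal(cell_distribution(e1, 2, 1)$mean, 11.6)
  expect_error(cell_distribution(m1, 3, 1), "genotype")
  expect_error(generating_model("M99"), "unknown")
})

test_that("moment matching reproduces the target mean and sd", {
  gm <- match_moments("GM", 11.6, 3.4)
  expect_equal(unname(gm["shape"]), (11.6 / 3.4)^2, tolerance = 1e-10)
  expect_equal(unname(gm["scale"]), 3.4^2 / 11.6, tolerance = 1e-10)
  # Weibull CV = 1 only at shape 1 (exponential)
  wb <- match_moments("WB", 5, 5)
  expect_equal(unname(wb["shape"]), 1, tolerance = 1e-6)
  # round trip across families and a grid of cells
  for (fam in c("WB", "BS", "GM")) {
    for (mn in c(8.2, 11.6, 16.3)) {
      for (s in c(1.7, 3.4, 5.1)) {
        par <- match_moments(fam, mn, s)
        mm <- teppld:::dist_moments(fam, par)
        expect_lt(abs(mm["mean"] - mn) / mn, 1e-6)
        expect_lt(abs(mm["sd"] - s) / s, 1e-6)
      }
    }
  }
  expect_error(match_moments("GM", -1, 2), "positive")
})

test_that("cohorts are reproducible and censoring behaves as designed", {
  m <- generating_model("M1")
  a <- sim_cohort(m, 400, seed = 11)
  b <- sim_cohort(m, 400, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$time, sim_cohort(m, 400, seed = 12)$time))
  expect_true(all(a$time > 0))
  expect_true(all(a$genotype %in% 0:2))
  expect_true(all(a$covariate %in% 1:2))
  expect_false(anyDuplicated(a$sample_id) > 0)
  # censored times are the (integer) observation ages
  cens <- a$time[a$event == 0]
  expect_true(all(cens == round(cens)))
  # censoring fraction near the design rate
  cf <- vapply(1:100, function(r) {
    mean(sim_cohort(m, 400, seed = replicate_seed(5, r))$event == 0)
  }, numeric(1))
  expect_gt(mean(cf), 0.38)
  expect_lt(mean(cf), 0.46)
})

test_that("non-normal families inherit the cell moments", {
  for (fam in c("WB", "BS", "GM")) {
    m <- generating_model("M1", family = fam)
    coh <- sim_cohort(m, 4000, seed = 21)
    ev <- teppld:::sim_event_ages(m, coh$genotype, coh$covariate)
    # event ages pooled across covariate: mixture of 11.6 and 14.6 cells
    expect_lt(abs(mean(ev) - 13.1), 0.25)
    expect_true(all(ev > 0))
  }
})

test_that("array-like MAF spectrum has the target moments and support", {
  withr::with_seed(6, {
    maf <- sample_chip_maf(2e5)
    expect_true(all(maf >= 0.03 & maf <= 0.5))
    expect_lt(abs(mean(maf) - 0.23), 3 * 0.14 / sqrt(2e5))
    expect_lt(abs(sd(maf) - 0.14), 0.002)
  })
})

test_that("replicate seeds are deterministic and within integer range", {
  s1 <- replicate_seed(1, 1:1000)
  expect_identical(s1, replicate_seed(1, 1:1000))
  expect_true(all(s1 >= 1 & s1 < 2^31))
  expect_identical(anyDuplicated(s1), 0L)
  expect_false(any(replicate_seed(2, 1:1000) == s1))
})
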