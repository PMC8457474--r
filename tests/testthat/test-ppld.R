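test_that("log likelihood ratio matches hand-computed values", {
  gam_null <- c(mu11 = 0.3, mu12 = 0.3, mu22 = 0.3,
                sd11 = 1.2, sd12 = 1.2, sd22 = 1.2)
  t <- c(-0.7, 0.1, 1.4)
  g <- c(0L, 1L, 2L)
  # equal means and SDs collapse the association model onto the mixture
  expect_equal(log_lr(gam_null, t, g, c(0.25, 0.5, 0.25)), 0)
  # direct density arithmetic: 2 individuals, mirrored configuration
  gam <- c(mu11 = -1, mu12 = 0, mu22 = 1, sd11 = 1, sd12 = 1, sd22 = 1)
  lr <- exp(log_lr(gam, c(-1, 1), c(0L, 2L), c(0.25, 0.5, 0.25)))
  by_hand <- (dnorm(0) / (0.25 * dnorm(0) + 0.5 * dnorm(1) + 0.25 * dnorm(2)))^2
  expect_equal(lr, by_hand, tolerance = 1e-12)
  expect_equal(round(lr, 2), 2.90)
  # mirror symmetry: negate phenotype, reverse labels, mirror gamma
  gam_m <- c(mu11 = -1, mu12 = 0, mu22 = 1, sd11 = 1, sd12 = 1.3, sd22 = 0.8)
  gam_r <- c(mu11 = -gam_m[["mu22"]], mu12 = -gam_m[["mu12"]],
             mu22 = -gam_m[["mu11"]], sd11 = gam_m[["sd22"]],
             sd12 = gam_m[["sd12"]], sd22 = gam_m[["sd11"]])
  t3 <- c(-0.5, 0.2, 0.9, -1.1)
  g3 <- c(0L, 1L, 2L, 1L)
  expect_equal(log_lr(gam_m, t3, g3, c(0.2, 0.5, 0.3)),
               log_lr(gam_r, -t3, 2L - g3, c(0.3, 0.5, 0.2)),
               tolerance = 1e-12)
  expect_error(log_lr(gam, c(NA, 1), c(0L, 2L)), "finite")
})

test_that("the PPLD transform has its exact algebraic properties", {
  pi <- 4e-4
  expect_identical(ppld_from_br(1, pi), pi)
  expect_identical(ppld_from_br(0, pi), 0)
  expect_identical(ppld_from_br(Inf, pi), 1)
  expect_equal(ppld_from_br((1 - pi) / pi, pi), 0.5, tolerance = 1e-12)
  br <- c(0.01, 0.5, 1, 3, 100, 1e6)
  expect_true(all(diff(ppld_from_br(br, pi)) > 0))
  expect_error(ppld_from_br(-1), ">= 0")
})

test_that("sequential updating multiplies evidence and is order-invariant", {
  pi <- 4e-4
  expect_equal(sequential_update(c(1, 1), pi)$ppld, pi)
  u <- sequential_update(c(10, 0.1), pi)
  expect_equal(u$br, 1, tolerance = 1e-12)
  expect_equal(u$ppld, pi, tolerance = 1e-12)
  expect_identical(u$n_datasets, 2L)
  a <- sequential_update(c(2.5, 0.3, 7))
  b <- sequential_update(c(7, 2.5, 0.3))
  expect_equal(a$br, b$br, tolerance = 1e-12)
  expect_equal(a$ppld, b$ppld, tolerance = 1e-12)
  # a neutral follow-up data set leaves the updated PPLD unchanged
  expect_equal(sequential_update(c(37.2, 1))$ppld, ppld_from_br(37.2))
  expect_error(sequential_update(numeric(0)), "empty")
})

test_that("monomorphic SNPs are evidence-neutral by construction", {
  t <- withr::with_seed(51, scale(rnorm(30))[, 1])
  b <- bayes_ratio(t, rep(0L, 30))
  expect_identical(b$br, 1)
  expect_identical(b$ppld, 4e-4)
  expect_identical(b$flag, "monomorphic")
})

test_that("quadrature agrees with a brute-force Monte-Carlo prior average", {
  for (i in 1:6) {
    withr::with_seed(600 + i, {
      n <- sample(8:20, 1)
      g <- sim_genotypes(n, runif(1, 0.2, 0.5))
      if (length(unique(g)) == 1) g[1:2] <- c(0L, 2L)
      t <- scale(rnorm(n, 0.3 * g, 1))[, 1]
    })
    b <- bayes_ratio(t, g, config = ppld_config(n_points = 8192))
    mc <- mc_bayes_ratio(t, g, n_mc = 1e5, seed = 600 + i)
    expect_lt(abs(b$br - mc$br), 3 * mc$se + 0.02 * mc$br)
  }
})

test_that("means-only mode with a point SD prior equals 3-D integration", {
  withr::with_seed(61, {
    g <- sim_genotypes(15, 0.4)
    g[1:2] <- c(0L, 2L)
    t <- scale(rnorm(15))[, 1]
  })
  prior <- trait_prior(sd_bounds = c(1, 1), means_only = TRUE)
  b <- bayes_ratio(t, g, prior, ppld_config(n_points = 8192))
  # oracle: plain MC over the three means with all SDs pinned at 1
  withr::with_seed(62, {
    p2 <- mean(g) / 2
    P <- c((1 - p2)^2, 2 * p2 * (1 - p2), p2^2)
    mu <- matrix(runif(3e5 * 3, -3, 3), 3e5)
    lr <- vapply(seq_len(3e5), function(j) {
      num <- sum(dnorm(t, mu[j, g + 1], 1, log = TRUE))
      den <- sum(log(P[1] * dnorm(t, mu[j, 1], 1) +
                       P[2] * dnorm(t, mu[j, 2], 1) +
                       P[3] * dnorm(t, mu[j, 3], 1)))
      exp(num - den)
    }, numeric(1))
  })
  expect_lt(abs(b$br - mean(lr)), 3 * sd(lr) / sqrt(3e5) + 0.02 * mean(lr))
})

test_that("relabeling alleles leaves the Bayes ratio unchanged", {
  coh <- sim_cohort(generating_model("M2", maf = 0.3), 300, seed = 71)
  res <- ote_residuals(coh)
  b1 <- bayes_ratio(res, coh$genotype)
  b2 <- bayes_ratio(res, 2L - coh$genotype)
  expect_identical(b1$maf_hat, b2$maf_hat)
  expect_equal(b1$log10br, b2$log10br, tolerance = 1e-12)
})

test_that("permuting the phenotype against genotypes destroys the signal", {
  coh <- sim_cohort(generating_model("M2"), 400, seed = 81)
  res <- ote_residuals(coh)
  l10 <- vapply(1:25, function(r) {
    perm <- withr::with_seed(810 + r, sample(res$residual))
    bayes_ratio(perm, coh$genotype,
                config = ppld_config(n_points = 2048))$log10br
  }, numeric(1))
  expect_lt(median(l10), 0)
})

test_that("scans are deterministic, filter low-MAF SNPs and survive errors", {
  coh <- sim_cohort(generating_model("M1"), 120, seed = 91)
  res <- ote_residuals(coh)
  G <- withr::with_seed(92, cbind(
    snp_a = sim_genotypes(120, 0.4),
    snp_dup = NA,
    snp_rare = c(rep(0L, 118), 1L, 1L),
    snp_mono = rep(0L, 120)))
  G[, "snp_dup"] <- G[, "snp_a"]
  sc <- ppld_scan(res, G, config = ppld_config(n_points = 1024))
  expect_identical(nrow(sc), 4L)
  expect_equal(sc$log10br[sc$snp_id == "snp_a"],
               sc$log10br[sc$snp_id == "snp_dup"])
  expect_identical(sc$flag[sc$snp_id == "snp_rare"], "low_maf")
  expect_true(is.na(sc$br[sc$snp_id == "snp_rare"]))
  expect_identical(sc$flag[sc$snp_id == "snp_mono"], "monomorphic")
  sc2 <- ppld_scan(res, G, config = ppld_config(n_points = 1024))
  expect_identical(sc, sc2)
})

test_that("the prior and configuration objects validate their inputs", {
  expect_error(trait_prior(sd_bounds = c(0, 1)))
  expect_error(trait_prior(mean_bounds = c(3, -3)))
  expect_error(ppld_config(pi = 0))
  cfg <- ppld_config()
  expect_identical(cfg$theta, 0)
  expect_identical(cfg$d_prime, 1)
  expect_identical(cfg$admixture, 1)
})
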