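# Independent oracles used across tests; none of these call the package's
# own integration or residual code paths.

# brute-force Monte-Carlo prior average of LR(gamma) over the uniform box;
# returns the estimate and its Monte-Carlo standard error
mc_bayes_ratio <- function(phenotype, genotypes, n_mc = 1e5,
                           mean_bounds = c(-3, 3), sd_bounds = c(0.3, 3),
                           seed = 1) {
  withr::with_seed(seed, {
    p2 <- mean(genotypes) / 2
    P <- c((1 - p2)^2, 2 * p2 * (1 - p2), p2^2)
    mu <- matrix(runif(n_mc * 3, mean_bounds[1], mean_bounds[2]), n_mc)
    sds <- matrix(runif(n_mc * 3, sd_bounds[1], sd_bounds[2]), n_mc)
    lr <- vapply(seq_len(n_mc), function(j) {
      num <- sum(dnorm(phenotype, mu[j, genotypes + 1], sds[j, genotypes + 1],
                       log = TRUE))
      den <- sum(log(P[1] * dnorm(phenotype, mu[j, 1], sds[j, 1]) +
                       P[2] * dnorm(phenotype, mu[j, 2], sds[j, 2]) +
                       P[3] * dnorm(phenotype, mu[j, 3], sds[j, 3])))
      exp(num - den)
    }, numeric(1))
    list(br = mean(lr), se = sd(lr) / sqrt(n_mc))
  })
}

# numerical-quadrature conditional mean E[T | T > c] for a Weibull
quad_conditional_mean <- function(shape, scale, c) {
  S <- function(t) exp(-(t / scale)^shape)
  c + integrate(S, c, Inf, rel.tol = 1e-10)$value / S(c)
}

# small deterministic cohort builder for io/cph edge tests
tiny_cohort <- function(n = 40, seed = 7, model = "M1", maf = 0.5) {
  sim_cohort(generating_model(model, maf = maf), n, seed = seed)
}
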