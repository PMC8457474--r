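# Synthetic cohort generation: HWE genotypes, binary covariate, event ages
# from the model's genotype x covariate cells, negative-binomial observation
# ages, censoring by comparison of the two.

#' Deterministic child seed for replicate r of an experiment
#'
#' Experiments draw each replicate under its own seed derived from
#' `(base_seed, r)`, so runs are reproducible replicate-by-replicate and can be
#' resumed or parallelized without changing results.
#'
#' @param base_seed Integer base seed.
#' @param r Replicate index (>= 1). May be a vector.
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
replicate_seed <- function(base_seed, r) {
  as.integer((((as.numeric(base_seed) %% 1000003) * 2039 +
                 (as.numeric(r) %% 1000003) * 9973 + 104729) %% 2147483629) + 1)
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency in `[0, 0.5]`.
#' @return Integer vector of minor-allele counts (0/1/2); genotype 2 has
#'   probability `maf^2`, genotype 1 `2 maf (1-maf)`, genotype 0 `(1-maf)^2`.
#' @export
sim_genotypes <- function(n, maf) {
  stopifnot(n >= 1)
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) || maf < 0 || maf > 0.5) {
    stop("`maf` must be in [0, 0.5]", call. = FALSE)
  }
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample.int(3L, n, replace = TRUE, prob = p) - 1L
}

#' Draw covariate levels
#'
#' Fixed law: exactly `floor(n/2)` individuals at level 1, the rest at level 2.
#' Random law: a per-replicate proportion `alpha` of level-2 individuals is
#' drawn from Normal(`alpha_mean`, `alpha_sd`) truncated to (0, 1), then levels
#' are assigned independently Bernoulli(`alpha`).
#'
#' @param n Number of individuals.
#' @param law `"fixed"` or `"random"`.
#' @param alpha_mean,alpha_sd Parameters of the random law (defaults 0.7, 0.1).
#' @return Integer vector of covariate levels in `{1, 2}`, with the drawn
#'   `alpha` attached as attribute `"alpha"` under the random law.
#' @export
sim_covariates <- function(n, law = c("fixed", "random"),
                           alpha_mean = 0.7, alpha_sd = 0.1) {
  law <- match.arg(law)
  stopifnot(n >= 1)
  if (law == "fixed") {
    n1 <- n %/% 2
    return(rep(c(1L, 2L), c(n1, n - n1)))
  }
  repeat {
    alpha <- stats::rnorm(1, alpha_mean, alpha_sd)
    if (alpha > 0 && alpha < 1) break
  }
  y <- 1L + (stats::runif(n) < alpha)
  attr(y, "alpha") <- alpha
  y
}

#' Draw observation ages from a negative-binomial law
#'
#' Ages at observation are negative-binomial counts (failures before the
#' `r`-th success; mean `r(1-p)/p` = 15 years at the defaults). Zero draws are
#' redrawn so that every observation age is positive.
#'
#' @param n Number of draws.
#' @param r,p Negative-binomial parameters (defaults 10, 0.4).
#' @return Positive integer-valued ages (years).
#' @export
sim_observation_age <- function(n, r = 10, p = 0.4) {
  stopifnot(n >= 1)
  out <- stats::rnbinom(n, size = r, prob = p)
  while (any(out == 0L)) {
    zero <- out == 0L
    out[zero] <- stats::rnbinom(sum(zero), size = r, prob = p)
  }
  out
}

# draw event ages for a vector of cells: inverse-CDF on the renormalized
# left-truncated normal for MoN; positive-support families need no truncation
sim_event_ages <- function(model, genotype, covariate) {
  n <- length(genotype)
  stopifnot(length(covariate) == n)
  te <- numeric(n)
  for (g in 0:2) {
    for (y in 1:2) {
      sel <- genotype == g & covariate == y
      m <- sum(sel)
      if (m == 0) next
      cell <- cell_distribution(model, g, y)
      u <- stats::runif(m)
      te[sel] <- switch(cell$family,
        MoN = {
          p0 <- stats::pnorm(0, cell$params[["mean"]], cell$params[["sd"]])
          stats::qnorm(p0 + u * (1 - p0), cell$params[["mean"]], cell$params[["sd"]])
        },
        WB = stats::qweibull(u, cell$params[["shape"]], cell$params[["scale"]]),
        GM = stats::qgamma(u, shape = cell$params[["shape"]],
                           scale = cell$params[["scale"]]),
        BS = qbs(u, cell$params[["alpha"]], cell$params[["beta"]])
      )
    }
  }
  te
}

#' Simulate a survival-phenotype cohort
#'
#' Draws, for each individual, a genotype under HWE at the model's MAF, a
#' covariate level under the model's covariate law, an event age from the
#' genotype x covariate cell distribution, and an independent negative-binomial
#' observation age. Individuals whose event age falls before their observation
#' age are observed events; the rest are censored at the observation age.
#'
#' @param model A [generating_model()].
#' @param n Cohort size (>= 2).
#' @param seed Optional integer seed; given `(model, n, seed)` the cohort is
#'   bit-reproducible and the global RNG state is untouched.
#' @return A tibble with columns `sample_id`, `genotype` (0/1/2), `covariate`
#'   (1/2), `time` (years > 0) and `event` (1 observed, 0 censored), carrying
#'   attributes `model_id`, `seed` and (random covariate law) `alpha`.
#' @examples
#' coh <- sim_cohort(generating_model("M1"), n = 400, seed = 1)
#' mean(coh$event == 0) # censoring fraction near 0.4
#' @export
sim_cohort <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "te_model"), n >= 2)
  draw <- function() {
    g <- sim_genotypes(n, model$maf)
    y <- sim_covariates(n, model$covariate_law)
    te <- sim_event_ages(model, g, y)
    to <- sim_observation_age(n, model$censor_r, model$censor_p)
    event <- as.integer(te < to)
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      genotype = g,
      covariate = as.integer(y),
      time = ifelse(event == 1L, te, as.numeric(to)),
      event = event
    ) -> out
    attr(out, "alpha") <- attr(y, "alpha")
    out
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "model_id") <- model$model_id
  attr(out, "seed") <- seed
  out
}

#' Draw minor allele frequencies mimicking a genotyping array
#'
#' Emulates the MAF spectrum of a common-variant SNP array after removal of
#' variants with MAF < 3%: a Beta distribution rescaled to (0.03, 0.5) with
#' parameters solved so the rescaled mean is 0.23 and sd 0.14.
#'
#' @param n_snps Number of SNPs.
#' @param mean,sd Target mean and sd of the rescaled distribution.
#' @param lower,upper Support bounds.
#' @return MAF vector in `[lower, upper]`.
#' @export
sample_chip_maf <- function(n_snps, mean = 0.23, sd = 0.14,
                            lower = 0.03, upper = 0.5) {
  stopifnot(n_snps >= 1, lower < mean, mean < upper)
  width <- upper - lower
  m <- (mean - lower) / width
  v <- (sd / width)^2
  if (v >= m * (1 - m)) stop("infeasible Beta moments", call. = FALSE)
  nu <- m * (1 - m) / v - 1
  lower + width * stats::rbeta(n_snps, m * nu, (1 - m) * nu)
}
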