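# The PPLD core: per-SNP Bayes ratio over the genotype-specific trait-model
# parameters gamma = (mu11, mu12, mu22, sd11, sd12, sd22), the PPLD rescaling,
# and sequential updating across data sets.
#
# With recombination fraction 0, D' = 1, admixture 1 and trait-locus allele
# frequency equal to the SNP allele frequency, the general trait-marker LD
# likelihood collapses so that the trait-locus genotype coincides with the
# observed SNP genotype; only that reduced form is implemented. The likelihood
# ratio at a trait-model point contrasts genotype-specific normal densities
# (association) with their HWE mixture (no association).

THETA_FIXED <- 0
DPRIME_FIXED <- 1
ADMIXTURE_FIXED <- 1

#' Uniform prior box over trait-model parameters
#'
#' The Bayes ratio averages the likelihood ratio over independent uniform
#' priors: each genotype-specific mean on `mean_bounds` and each
#' genotype-specific SD on `sd_bounds`, in standardized-residual units, with no
#' ordering constraint (so recessive, additive and dominant configurations are
#' all covered). In means-only mode the three SDs are collapsed to a single
#' shared value; a degenerate `sd_bounds` (equal endpoints) fixes that value.
#'
#' @param mean_bounds Length-2 interval for each genotypic mean.
#' @param sd_bounds Length-2 interval for each genotypic SD (lower bound > 0).
#' @param means_only Collapse the three SDs to one shared dimension.
#' @return An object of class `ppld_prior`.
#' @export
trait_prior <- function(mean_bounds = c(-3, 3), sd_bounds = c(0.3, 3),
                        means_only = FALSE) {
  stopifnot(length(mean_bounds) == 2, length(sd_bounds) == 2,
            all(is.finite(mean_bounds)), all(is.finite(sd_bounds)),
            mean_bounds[1] < mean_bounds[2], sd_bounds[1] > 0,
            sd_bounds[1] <= sd_bounds[2])
  structure(list(mean_bounds = as.numeric(mean_bounds),
                 sd_bounds = as.numeric(sd_bounds),
                 means_only = isTRUE(means_only)),
            class = "ppld_prior")
}

#' PPLD analysis configuration
#'
#' @param pi Prior probability that a random SNP is in detectable LD with a
#'   trait locus (default 0.0004).
#' @param n_points Number of deterministic quasi-random integration points for
#'   the Bayes-ratio integral (default 4096).
#' @param tol_log10 Flag threshold for the split-half integration-error
#'   estimate, in log10 Bayes-ratio units (default 1).
#' @param maf_min Minimum sample MAF for a SNP to be analyzed in a scan
#'   (default 0.03); SNPs below the floor are flagged and skipped.
#' @return An object of class `ppld_config`. The recombination fraction (0),
#'   D' (1) and admixture (1) are fixed constants of the reduced likelihood
#'   and are not configurable.
#' @export
ppld_config <- function(pi = 4e-4, n_points = 4096, tol_log10 = 1,
                        maf_min = 0.03) {
  stopifnot(pi > 0, pi < 1, n_points >= 64)
  structure(list(pi = pi, n_points = as.integer(n_points),
                 tol_log10 = tol_log10, maf_min = maf_min,
                 theta = THETA_FIXED, d_prime = DPRIME_FIXED,
                 admixture = ADMIXTURE_FIXED),
            class = "ppld_config")
}

# ---- low-level numerics ----------------------------------------------------

# Halton sequence (bases 2..13), skipping an initial run; deterministic
halton_seq <- function(n, dims, skip = 100) {
  bases <- c(2, 3, 5, 7, 11, 13)[seq_len(dims)]
  out <- matrix(0, n, dims)
  idx <- seq_len(n) + skip
  for (d in seq_len(dims)) {
    b <- bases[d]; im <- idx; f <- 1; r <- numeric(n)
    repeat {
      f <- f / b
      r <- r + f * (im %% b)
      im <- im %/% b
      if (all(im == 0)) break
    }
    out[, d] <- r
  }
  out
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

dtnorm_log <- function(x, m, s, lo, hi) {
  stats::dnorm(x, m, s, log = TRUE) -
    log(stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s))
}

qtnorm <- function(u, m, s, lo, hi) {
  plo <- stats::pnorm(lo, m, s)
  phi <- stats::pnorm(hi, m, s)
  stats::qnorm(plo + u * (phi - plo), m, s)
}

# batch log likelihood ratio at a matrix of trait-model points
# mu, sd3: M x 3; t standardized phenotype; g genotypes 0/1/2; P genotype freqs
eval_loglr_batch <- function(mu, sd3, t, g, P) {
  n <- length(t)
  M <- nrow(mu)
  num <- numeric(M)
  Dsum <- matrix(0, n, M)
  for (k in 1:3) {
    Z <- outer(t, mu[, k], "-") * rep(1 / sd3[, k], each = n)
    logD <- -0.9189385332046727 - rep(log(sd3[, k]), each = n) - 0.5 * Z * Z
    ik <- which(g == k - 1L)
    if (length(ik)) num <- num + colSums(logD[ik, , drop = FALSE])
    Dsum <- Dsum + P[k] * exp(logD)
  }
  num - colSums(log(Dsum))
}

# scalar log LR at a parameter vector th = (mu, sds...) under a prior layout;
# avoids the batch machinery for the many small calls of the mode search
loglr_point <- function(th, t, g, P, prior) {
  gam <- expand_theta(th, prior)
  num <- 0
  den <- 0
  for (k in 1:3) {
    ld <- stats::dnorm(t, gam$mu[k], gam$sd[k], log = TRUE)
    ik <- g == k - 1L
    if (any(ik)) num <- num + sum(ld[ik])
    den <- den + P[k] * exp(ld)
  }
  num - sum(log(den))
}

# theta layout: 3 means, then 3 sds | 1 shared sd | none (degenerate bounds)
n_sd_dims <- function(prior) {
  if (prior$sd_bounds[1] == prior$sd_bounds[2]) 0L
  else if (prior$means_only) 1L else 3L
}

expand_theta <- function(th, prior) {
  nsd <- n_sd_dims(prior)
  sd <- switch(as.character(nsd),
    "0" = rep(prior$sd_bounds[1], 3),
    "1" = rep(th[4], 3),
    "3" = th[4:6])
  list(mu = th[1:3], sd = sd)
}

#' Log likelihood ratio at a single trait-model point
#'
#' The association model gives individual `i` the normal density with the mean
#' and SD of its own genotype; the no-association model gives every individual
#' the HWE-weighted mixture of the three genotype densities. The returned value
#' is the sum over individuals of the log of their ratio.
#'
#' @param gamma Named vector `c(mu11, mu12, mu22, sd11, sd12, sd22)`
#'   (standardized units; indices are minor-allele counts 0/1/2).
#' @param phenotype Standardized residual phenotype vector.
#' @param genotypes Minor-allele counts, 0/1/2, same length.
#' @param genotype_freqs Optional 3-vector of genotype probabilities (must sum
#'   to 1); defaults to HWE frequencies at the sample allele frequency.
#' @return Log likelihood ratio (natural log).
#' @examples
#' g <- c(0, 2); t <- c(-1, 1)
#' gamma <- c(mu11 = -1, mu12 = 0, mu22 = 1, sd11 = 1, sd12 = 1, sd22 = 1)
#' exp(log_lr(gamma, t, g, c(0.25, 0.5, 0.25))) # ~ 2.90
#' @export
log_lr <- function(gamma, phenotype, genotypes, genotype_freqs = NULL) {
  nm <- c("mu11", "mu12", "mu22", "sd11", "sd12", "sd22")
  if (!all(nm %in% names(gamma))) {
    stop("`gamma` must carry names ", paste(nm, collapse = ", "), call. = FALSE)
  }
  gamma <- gamma[nm]
  if (any(gamma[4:6] <= 0)) stop("genotypic SDs must be > 0", call. = FALSE)
  if (any(!is.finite(phenotype))) {
    stop("phenotype must be finite", call. = FALSE)
  }
  if (length(phenotype) != length(genotypes)) stop("length mismatch", call. = FALSE)
  if (!all(genotypes %in% 0:2)) stop("genotypes must be 0/1/2", call. = FALSE)
  if (is.null(genotype_freqs)) {
    p <- mean(genotypes) / 2
    genotype_freqs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  }
  if (abs(sum(genotype_freqs) - 1) > 1e-8) {
    stop("genotype_freqs must sum to 1", call. = FALSE)
  }
  c(eval_loglr_batch(matrix(gamma[1:3], 1), matrix(gamma[4:6], 1),
                     phenotype, as.integer(genotypes), genotype_freqs))
}

# ---- Bayes ratio -----------------------------------------------------------

# deterministic quasi-random defensive importance sampling of the prior
# average of LR(gamma): 60% uniform box points for the diffuse mass, 20% wide
# and 20% narrow truncated-normal points centered at the integrand mode for
# the data-driven peak (mode by Nelder-Mead, widths from the numerical
# Hessian). Returns log BR plus split-half diagnostics.
br_integrate <- function(t, g, P, prior, n_points) {
  mb <- prior$mean_bounds
  sb <- prior$sd_bounds
  nsd <- n_sd_dims(prior)
  d <- 3L + nsd
  lo <- c(rep(mb[1], 3), rep(sb[1], nsd))
  hi <- c(rep(mb[2], 3), rep(sb[2], nsd))

  # start at group moments, clamped into the box
  grp_m <- vapply(0:2, function(k) {
    x <- t[g == k]
    if (length(x) >= 2) mean(x) else 0
  }, numeric(1))
  grp_s <- vapply(0:2, function(k) {
    x <- t[g == k]
    if (length(x) >= 2) max(stats::sd(x), sb[1] + 0.05) else 1
  }, numeric(1))
  start <- c(pmin(pmax(grp_m, mb[1]), mb[2]),
             switch(as.character(nsd),
                    "0" = numeric(0),
                    "1" = min(max(mean(grp_s), sb[1]), sb[2]),
                    "3" = pmin(pmax(grp_s, sb[1]), sb[2])))

  negf <- function(th) -loglr_point(pmin(pmax(th, lo), hi), t, g, P, prior)
  op <- stats::optim(start, negf, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-8))
  mode <- pmin(pmax(op$par, lo + 1e-6), hi - 1e-6)

  # diagonal curvature -> proposal widths
  h <- 1e-3
  f0 <- -negf(mode)
  wid <- vapply(seq_len(d), function(j) {
    e <- rep(0, d); e[j] <- h
    cur <- (-negf(mode + e) - 2 * f0 - negf(mode - e)) / h^2
    if (is.finite(cur) && cur < -1e-4) sqrt(-1 / cur) else 0.5
  }, numeric(1))
  w_narrow <- pmin(pmax(2.5 * wid, 0.03), 3)
  w_wide <- pmin(pmax(8 * wid, 0.3), 4)

  M <- n_points
  wts <- c(0.6, 0.2, 0.2)
  n1 <- round(wts[1] * M); n2 <- round(wts[2] * M); n3 <- M - n1 - n2
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2); i3 <- n1 + n2 + seq_len(n3)
  H <- halton_seq(M, d)

  th <- matrix(0, M, d)
  for (j in seq_len(d)) {
    th[i1, j] <- lo[j] + H[i1, j] * (hi[j] - lo[j])
    th[i2, j] <- qtnorm(H[i2, j], mode[j], w_wide[j], lo[j], hi[j])
    th[i3, j] <- qtnorm(H[i3, j], mode[j], w_narrow[j], lo[j], hi[j])
  }

  logprior <- -sum(log(hi - lo))
  lq_wide <- numeric(M); lq_narrow <- numeric(M)
  for (j in seq_len(d)) {
    lq_wide <- lq_wide + dtnorm_log(th[, j], mode[j], w_wide[j], lo[j], hi[j])
    lq_narrow <- lq_narrow + dtnorm_log(th[, j], mode[j], w_narrow[j], lo[j], hi[j])
  }
  Q1 <- log(wts[1]) + logprior
  Q2 <- log(wts[2]) + lq_wide
  Q3 <- log(wts[3]) + lq_narrow
  mq <- pmax(Q1, Q2, Q3)
  logq <- mq + log(exp(Q1 - mq) + exp(Q2 - mq) + exp(Q3 - mq))

  mu <- th[, 1:3, drop = FALSE]
  sd3 <- switch(as.character(nsd),
    "0" = matrix(sb[1], M, 3),
    "1" = matrix(th[, 4], M, 3),
    "3" = th[, 4:6, drop = FALSE])
  llr <- eval_loglr_batch(mu, sd3, t, g, P)
  x <- llr + logprior - logq

  logbr <- logsumexp(x) - log(M)
  h1 <- logsumexp(x[seq(1, M, 2)]) - log(length(seq(1, M, 2)))
  h2 <- logsumexp(x[seq(2, M, 2)]) - log(length(seq(2, M, 2)))
  list(logbr = logbr,
       log10br_se = abs(h1 - h2) / (2 * log(10)),
       n_eval = M)
}

#' Bayes ratio and PPLD for one SNP
#'
#' Computes `BR = integral of LR(gamma) f(gamma) d gamma`, the average of the
#' association/no-association likelihood ratio under the uniform prior box,
#' by a deterministic quasi-random quadrature, then rescales it to the
#' posterior probability of linkage disequilibrium
#' `PPLD = pi BR / (pi BR + 1 - pi)`. A monomorphic SNP carries no evidence
#' either way and returns `BR = 1` exactly.
#'
#' @param phenotype Standardized residual phenotype (numeric vector), or a
#'   data frame with a `residual` column, e.g. the output of
#'   [ote_residuals()].
#' @param genotypes Minor-allele counts 0/1/2; `NA`s are dropped pairwise.
#' @param prior A [trait_prior()].
#' @param config A [ppld_config()].
#' @return A one-row tibble: `br`, `log10br`, `ppld`, `n_used`, `maf_hat`,
#'   `n_eval`, `log10br_se` (split-half integration-error estimate), `flag`
#'   (`"ok"`, `"monomorphic"`, or `"tolerance"` when the error estimate
#'   exceeds `config$tol_log10`).
#' @examples
#' coh <- sim_cohort(generating_model("M2"), 200, seed = 1)
#' res <- ote_residuals(coh)
#' bayes_ratio(res, coh$genotype)
#' @export
bayes_ratio <- function(phenotype, genotypes, prior = trait_prior(),
                        config = ppld_config()) {
  if (is.data.frame(phenotype)) {
    if (!"residual" %in% names(phenotype)) {
      stop("data frame `phenotype` needs a `residual` column", call. = FALSE)
    }
    phenotype <- phenotype$residual
  }
  stopifnot(inherits(prior, "ppld_prior"), inherits(config, "ppld_config"))
  if (length(phenotype) != length(genotypes)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(genotypes) & !is.na(phenotype)
  t <- phenotype[keep]
  g <- as.integer(genotypes[keep])
  if (any(!is.finite(t))) stop("phenotype must be finite", call. = FALSE)
  if (!all(g %in% 0:2)) stop("genotypes must be 0/1/2 or NA", call. = FALSE)
  n <- length(t)
  if (n < 2) stop("need at least 2 complete observations", call. = FALSE)

  # canonical orientation: count the minor allele, so that relabeling the
  # alleles (g -> 2 - g) computes the identical integral
  if (mean(g) / 2 > 0.5) g <- 2L - g
  p2 <- mean(g) / 2
  maf_hat <- min(p2, 1 - p2)
  if (length(unique(g)) == 1L) {
    return(br_result(1, 0, config$pi, n, maf_hat, 0L, 0, "monomorphic"))
  }
  P <- c((1 - p2)^2, 2 * p2 * (1 - p2), p2^2)
  quad <- br_integrate(t, g, P, prior, config$n_points)
  flag <- if (quad$log10br_se > config$tol_log10) "tolerance" else "ok"
  br_result(exp(quad$logbr), quad$logbr / log(10), config$pi, n, maf_hat,
            quad$n_eval, quad$log10br_se, flag)
}

br_result <- function(br, log10br, pi, n_used, maf_hat, n_eval, se, flag) {
  tibble::tibble(
    br = br, log10br = log10br, ppld = ppld_from_br(br, pi),
    n_used = as.integer(n_used), maf_hat = maf_hat,
    n_eval = as.integer(n_eval), log10br_se = se, flag = flag
  )
}

#' PPLD from a Bayes ratio
#'
#' `PPLD = pi BR / (pi BR + 1 - pi)`: the posterior probability of trait-SNP
#' association given prior `pi`. Strictly increasing in `br`; equals `pi` at
#' `br = 1`.
#'
#' @param br Nonnegative Bayes ratio(s).
#' @param pi Prior probability of detectable LD (default 0.0004).
#' @return Probability in `[0, 1)`.
#' @export
ppld_from_br <- function(br, pi = 4e-4) {
  if (any(br < 0, na.rm = TRUE)) stop("`br` must be >= 0", call. = FALSE)
  stopifnot(pi > 0, pi < 1)
  ifelse(is.infinite(br), 1, pi * br / (pi * br + 1 - pi))
}

#' Sequential updating of Bayes ratios across data sets
#'
#' Evidence accumulates by multiplying the per-data-set Bayes ratios and
#' applying the PPLD transform to the product; the result is order-invariant.
#'
#' @param br Vector of nonnegative Bayes ratios, one per data set.
#' @param pi Prior probability of detectable LD.
#' @return A one-row tibble: `br` (product), `log10br`, `ppld`, `n_datasets`.
#' @export
sequential_update <- function(br, pi = 4e-4) {
  if (length(br) == 0) stop("empty Bayes-ratio list", call. = FALSE)
  if (any(br < 0, na.rm = TRUE)) stop("`br` must be >= 0", call. = FALSE)
  n_sets <- length(br)
  l10 <- sum(log10(br))
  prod_br <- exp(sum(log(br)))
  tibble::tibble(br = prod_br,
                 log10br = l10,
                 ppld = ppld_from_br(prod_br, pi),
                 n_datasets = n_sets)
}

#' Per-SNP PPLD scan
#'
#' Runs [bayes_ratio()] for every SNP of a genotype matrix against one residual
#' phenotype (the covariate preprocessing is genotype-independent, so residuals
#' are computed once per cohort). SNPs whose sample MAF falls below
#' `config$maf_min` are flagged `"low_maf"` and skipped; per-SNP errors are
#' recorded as `"error"` rows and the scan continues.
#'
#' @param phenotype Standardized residuals (vector, or data frame with a
#'   `residual` column).
#' @param genotypes Matrix or data frame, samples in rows and SNPs in columns,
#'   entries 0/1/2 or `NA`.
#' @param prior A [trait_prior()].
#' @param config A [ppld_config()].
#' @return A tibble with one row per SNP: `snp_id` plus the [bayes_ratio()]
#'   columns.
#' @export
ppld_scan <- function(phenotype, genotypes, prior = trait_prior(),
                      config = ppld_config()) {
  if (is.data.frame(phenotype)) phenotype <- phenotype$residual
  G <- as.matrix(genotypes)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  purrr::map_dfr(seq_len(ncol(G)), function(j) {
    gj <- G[, j]
    keep <- !is.na(gj)
    p2 <- mean(gj[keep]) / 2
    maf <- min(p2, 1 - p2)
    mono <- length(unique(gj[keep])) <= 1L
    row <- if (!mono && maf < config$maf_min) {
      br_result(NA_real_, NA_real_, config$pi, sum(keep), maf, 0L, 0, "low_maf")
    } else {
      tryCatch(bayes_ratio(phenotype, gj, prior, config),
               error = function(e) {
                 br_result(NA_real_, NA_real_, config$pi, sum(keep), maf, 0L, 0,
                           "error")
               })
    }
    dplyr::bind_cols(tibble::tibble(snp_id = colnames(G)[j]), row)
  })
}
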