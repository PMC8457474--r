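# Generating models: genotype x covariate trait distributions on the standard
# normal scale, anchored to years via the loss-of-ambulation reference
# (mean 11.6 y, sd 3.4 y for the y = 1 group).

ANCHOR_MEAN <- 11.6
ANCHOR_SD <- 3.4
COVARIATE_OFFSET_YEARS <- 3

# per-model standard-scale cells; rows genotype 0/1/2 = minor-allele count
.model_table <- local({
  m <- function(mu1, sd1, mu2 = mu1, sd2 = sd1, offset = COVARIATE_OFFSET_YEARS,
                mode = "additive") {
    list(mu_y1 = mu1, sd_y1 = sd1, mu_y2 = mu2, sd_y2 = sd2,
         covariate_offset_years = offset, mode = mode)
  }
  list(
    M1 = m(c(0, 0, 0), c(1, 1, 1)),
    M2 = m(c(-0.5, 0, 0.5), c(1, 1, 1)),
    M3 = m(c(-0.5, 0, 0.5), c(1.25, 1.25, 1.25)),
    M4 = m(c(-0.5, 0.5, 0.5), c(1.25, 1.25, 1.25), mode = "dominant"),
    M5 = m(c(-0.5, -0.5, 0.5), c(1.25, 1.25, 1.25), mode = "recessive"),
    M6 = m(c(-0.5, 0, 0.5), c(0.5, 1, 1.5)),
    M7 = m(c(0, 0, 0), c(0.5, 1, 1.5)),
    M8 = m(c(-0.5, 0, 0.5), c(1, 1, 1),
           mu2 = c(1.26, 1.76, 2.26), sd2 = c(2, 2, 2), offset = 0),
    Epi1 = m(c(0, 0, 0), c(1, 1, 1), mu2 = c(-0.5, 0, 0.5)),
    Epi2 = m(c(0, 0, 0), c(1, 1, 1), mu2 = c(-0.5, 0.5, 0.5), mode = "dominant"),
    Epi3 = m(c(0, 0, 0), c(1, 1, 1), mu2 = c(-0.5, -0.5, 0.5), mode = "recessive"),
    Epi4 = m(c(0, 0, 0), c(1, 1, 1), sd2 = c(2, 1, 1)),
    Epi5 = m(c(-0.5, 0, 0), c(1, 1, 1), mu2 = c(-0.75, 0, 0), mode = "dominant"),
    Epi6 = m(c(-0.5, 0, 0), c(1, 1, 1), sd2 = c(1.5, 1, 1), mode = "dominant"),
    Epi7 = m(c(-0.5, 0, 0), c(1, 1, 1), mu2 = c(-0.75, 0, 0), sd2 = c(1.5, 1, 1),
             mode = "dominant")
  )
})

#' Construct a cohort generating model
#'
#' Returns the trait-generating model for one of the built-in simulation
#' scenarios: the null model `"M1"`, the baseline association models
#' `"M2"`--`"M8"`, or the covariate-by-genotype interaction (epistasis) models
#' `"Epi1"`--`"Epi7"`. Each model specifies, per genotype (minor-allele count
#' 0/1/2) and binary covariate level (`y` in 1/2), the mean and standard
#' deviation of the event-age distribution on the standard-normal scale. The
#' standard scale maps to years as `11.6 + 3.4 * z`, with 3 years added to the
#' `y = 2` means (except `"M8"`, whose `y = 2` cells are specified directly).
#'
#' @param model_id One of `"M1"`..`"M8"`, `"Epi1"`..`"Epi7"`.
#' @param family Event-age distribution family: `"MoN"` (mixture of normals,
#'   i.e. per-cell truncated normal), or `"WB"`, `"BS"`, `"GM"` (Weibull,
#'   Birnbaum-Saunders, Gamma matched to the normal cell's untruncated years
#'   mean and sd).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param covariate_law `"fixed"` (exactly half of the cohort at each covariate
#'   level) or `"random"` (per-replicate proportion of `y = 2` drawn from
#'   Normal(0.7, 0.1) truncated to (0, 1)). Defaults to `"random"` for the Epi
#'   models and `"fixed"` otherwise.
#' @param censor_r,censor_p Negative-binomial observation-age parameters
#'   (number of successes and success probability; mean `r(1-p)/p` = 15 years).
#'
#' @return An object of class `te_model`: a list with fields `model_id`,
#'   `family`, `maf`, `mu` and `sd` (3 x 2 matrices, genotype by covariate, on
#'   the standard scale), `covariate_offset_years`, `covariate_law`,
#'   `censor_r`, `censor_p`, `mode` (the generating mode of inheritance used
#'   for mode-matched Cox analyses), and `anchor` (years-scale anchor).
#' @examples
#' m <- generating_model("M2")
#' cell_distribution(m, genotype = 2, covariate = 2)$mean # 11.6 + 3.4*0.5 + 3
#' @export
generating_model <- function(model_id, family = c("MoN", "WB", "BS", "GM"),
                             maf = 0.5, covariate_law = NULL,
                             censor_r = 10, censor_p = 0.4) {
  family <- match.arg(family)
  if (!model_id %in% names(.model_table)) {
    stop("unknown model_id: ", model_id, "; expected one of ",
         paste(names(.model_table), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf > 0.5) {
    stop("`maf` must be a single value in (0, 0.5]", call. = FALSE)
  }
  if (is.null(covariate_law)) {
    covariate_law <- if (grepl("^Epi", model_id)) "random" else "fixed"
  }
  covariate_law <- match.arg(covariate_law, c("fixed", "random"))
  tab <- .model_table[[model_id]]
  structure(list(
    model_id = model_id,
    family = family,
    maf = maf,
    mu = cbind(y1 = tab$mu_y1, y2 = tab$mu_y2),
    sd = cbind(y1 = tab$sd_y1, y2 = tab$sd_y2),
    covariate_offset_years = tab$covariate_offset_years,
    covariate_law = covariate_law,
    censor_r = censor_r,
    censor_p = censor_p,
    mode = tab$mode,
    anchor = c(mean = ANCHOR_MEAN, sd = ANCHOR_SD)
  ), class = "te_model")
}

#' @export
print.te_model <- function(x, ...) {
  cat("<te_model> ", x$model_id, " (", x$family, "), MAF = ", x$maf,
      ", covariate law = ", x$covariate_law, "\n", sep = "")
  cat("standard-scale means (sds), genotype 0/1/2:\n")
  for (y in 1:2) {
    cat("  y =", y, ": ",
        paste0(format(x$mu[, y]), " (", format(x$sd[, y]), ")", collapse = "  "),
        if (y == 2 && x$covariate_offset_years > 0)
          paste0("  [+", x$covariate_offset_years, " y]") else "",
        "\n")
  }
  invisible(x)
}

#' Event-age distribution for one genotype x covariate cell
#'
#' Maps a model cell from the standard-normal scale to the years scale and, for
#' the non-normal families, matches the named 2-parameter family to the
#' untruncated years-scale mean and sd. The `"MoN"` family is a normal
#' left-truncated at 0 (a > 3 sigma event at the anchor scale, so truncation is
#' numerically negligible for the moments).
#'
#' @param model A [generating_model()].
#' @param genotype Minor-allele count, 0/1/2.
#' @param covariate Covariate level, 1 or 2.
#' @return A list with `family`, `params` (named parameter vector), and the
#'   targeted untruncated years-scale `mean` and `sd`.
#' @export
cell_distribution <- function(model, genotype, covariate) {
  stopifnot(inherits(model, "te_model"))
  if (!genotype %in% 0:2) stop("genotype must be 0, 1 or 2", call. = FALSE)
  if (!covariate %in% 1:2) stop("covariate must be 1 or 2", call. = FALSE)
  g <- genotype + 1L
  mu_y <- unname(model$mu[g, covariate])
  sd_y <- unname(model$sd[g, covariate])
  mean_years <- ANCHOR_MEAN + ANCHOR_SD * mu_y +
    if (covariate == 2L) model$covariate_offset_years else 0
  sd_years <- ANCHOR_SD * sd_y
  params <- switch(model$family,
    MoN = c(mean = mean_years, sd = sd_years),
    match_moments(model$family, mean_years, sd_years)
  )
  list(family = model$family, params = params,
       mean = mean_years, sd = sd_years)
}

#' Match a two-parameter positive distribution to a mean and sd
#'
#' Finds the Weibull (`"WB"`), Birnbaum-Saunders (`"BS"`) or Gamma (`"GM"`)
#' parameters whose distribution has the requested mean and standard
#' deviation. Gamma uses the closed form `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`; Weibull and Birnbaum-Saunders are solved numerically
#' from their coefficient-of-variation equations to relative error below 1e-9.
#'
#' @param family `"WB"`, `"BS"` or `"GM"`.
#' @param mean,sd Target moments (years), both > 0.
#' @return Named parameter vector: `shape`/`scale` for WB and GM,
#'   `alpha`/`beta` for BS.
#' @examples
#' match_moments("GM", 11.6, 3.4) # shape ~ 11.64, scale ~ 0.9966
#' @export
match_moments <- function(family, mean, sd) {
  family <- match.arg(family, c("WB", "BS", "GM"))
  if (!is.finite(mean) || !is.finite(sd) || mean <= 0 || sd <= 0) {
    stop("`mean` and `sd` must be positive and finite", call. = FALSE)
  }
  cv2 <- (sd / mean)^2
  switch(family,
    GM = c(shape = mean^2 / sd^2, scale = sd^2 / mean),
    WB = {
      f <- function(lk) {
        k <- exp(lk)
        lgamma(1 + 2 / k) - 2 * lgamma(1 + 1 / k) - log1p(cv2)
      }
      sol <- tryCatch(
        stats::uniroot(f, lower = log(0.05), upper = log(500),
                       tol = .Machine$double.eps^0.5),
        error = function(e) stop("Weibull moment match failed for mean = ",
                                 mean, ", sd = ", sd, ": ", conditionMessage(e),
                                 call. = FALSE)
      )
      k <- exp(sol$root)
      c(shape = k, scale = mean / gamma(1 + 1 / k))
    },
    BS = {
      # mean = beta (1 + a^2/2), var = (a beta)^2 (1 + 5 a^2/4); solve for u = a^2
      f <- function(lu) {
        u <- exp(lu)
        log(u) + log1p(1.25 * u) - 2 * log1p(u / 2) - log(cv2)
      }
      sol <- tryCatch(
        stats::uniroot(f, lower = log(1e-10), upper = log(1e4),
                       tol = .Machine$double.eps^0.5),
        error = function(e) stop("Birnbaum-Saunders moment match failed: ",
                                 conditionMessage(e), call. = FALSE)
      )
      u <- exp(sol$root)
      c(alpha = sqrt(u), beta = mean / (1 + u / 2))
    }
  )
}

# Birnbaum-Saunders helpers (fatigue-life distribution): closed-form quantile
# via T = beta * (a z/2 + sqrt((a z/2)^2 + 1))^2 with z standard normal.
qbs <- function(p, alpha, beta) {
  z <- stats::qnorm(p)
  beta * (alpha * z / 2 + sqrt((alpha * z / 2)^2 + 1))^2
}

bs_moments <- function(alpha, beta) {
  c(mean = beta * (1 + alpha^2 / 2),
    sd = alpha * beta * sqrt(1 + 1.25 * alpha^2))
}

# mean/sd realized by a matched parameter set (round-trip check helper)
dist_moments <- function(family, params) {
  switch(family,
    MoN = c(mean = unname(params["mean"]), sd = unname(params["sd"])),
    GM = c(mean = unname(params["shape"] * params["scale"]),
           sd = unname(sqrt(params["shape"]) * params["scale"])),
    WB = {
      k <- params[["shape"]]; lam <- params[["scale"]]
      m <- lam * gamma(1 + 1 / k)
      v <- lam^2 * (gamma(1 + 2 / k) - gamma(1 + 1 / k)^2)
      c(mean = m, sd = sqrt(v))
    },
    BS = bs_moments(params[["alpha"]], params[["beta"]])
  )
}
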