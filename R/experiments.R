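# Simulation studies: null calibration and empirical thresholds, power and
# robustness across generating families, epistasis stratification, replication
# versus sequential updating, and a scaled genome-scan mimic. Every study is
# driven by per-replicate child seeds from replicate_seed(), so results are
# bit-reproducible for a given (arguments, base_seed).

resolve_mode <- function(mode, model) {
  if (identical(mode, "generating")) model$mode else
    match.arg(mode, c("additive", "recessive", "dominant"))
}

# one cohort -> requested statistics (CPH P under `mode`, TE-PPLD on
# standardized stratified OTE residuals)
analyze_cohort <- function(coh, statistics, mode, prior, config) {
  out <- list(cph_P = NA_real_, log10br = NA_real_, ppld = NA_real_,
              br = NA_real_)
  if ("cph" %in% statistics) {
    fit <- cph_p(coh, mode)
    out$cph_P <- if (fit$degenerate) NA_real_ else fit$P
  }
  if ("ppld" %in% statistics) {
    res <- ote_residuals(coh)
    b <- bayes_ratio(res, coh$genotype, prior, config)
    out$log10br <- b$log10br
    out$ppld <- b$ppld
    out$br <- b$br
  }
  out
}

#' Empirical threshold at the top-k order statistic
#'
#' Returns the k-th largest value, the cutoff that demarcates the top `k`
#' scores of an empirical null distribution.
#'
#' @param values Statistic values.
#' @param k Rank, `1 <= k <= length(values)`.
#' @return The k-th largest value.
#' @export
threshold_top_k <- function(values, k) {
  if (k < 1 || k > length(values)) stop("`k` out of range", call. = FALSE)
  sort(values, decreasing = TRUE)[k]
}

#' Null-calibration study
#'
#' Simulates null (no-association) cohorts at one or more sample sizes and
#' computes the requested statistics per replicate, for studying the sampling
#' distributions under H0: the CPH `-log10(p)` distribution is stable in `N`,
#' while the TE-PPLD distribution shifts towards evidence against association
#' as `N` grows.
#'
#' @param n_reps Replicates per sample size.
#' @param sample_sizes Cohort sizes.
#' @param family Generating family (`"MoN"`, `"WB"`, `"BS"`, `"GM"`).
#' @param maf Minor allele frequency.
#' @param statistics Subset of `c("cph", "ppld")`.
#' @param mode Genotype coding for CPH (default additive under H0).
#' @param base_seed Base seed; replicate `r` at size `N` uses
#'   `replicate_seed(base_seed + N, r)`.
#' @param prior,config PPLD settings.
#' @return Tibble: `N`, `rep`, `seed`, `cph_P`, `log10br`, `ppld`.
#' @export
null_study <- function(n_reps, sample_sizes = c(200, 400, 800),
                       family = "MoN", maf = 0.5,
                       statistics = c("cph", "ppld"), mode = "additive",
                       base_seed = 1, prior = trait_prior(),
                       config = ppld_config()) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  purrr::map_dfr(sample_sizes, function(N) {
    model <- generating_model("M1", family = family, maf = maf)
    purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- replicate_seed(base_seed + N, r)
      coh <- sim_cohort(model, N, seed = s)
      a <- withr::with_seed(s + 1L,
        analyze_cohort(coh, statistics, mode, prior, config))
      tibble::tibble(N = N, rep = r, seed = s, cph_P = a$cph_P,
                     log10br = a$log10br, ppld = a$ppld)
    })
  })
}

#' @rdname null_study
#' @param results Output of [null_study()].
#' @param pi PPLD prior probability.
#' @export
null_summary <- function(results, pi = 4e-4) {
  dplyr::summarise(
    dplyr::group_by(results, .data$N),
    n_reps = dplyr::n(),
    frac_ppld_gt_pi = mean(.data$ppld > pi, na.rm = TRUE),
    median_log10br = stats::median(.data$log10br, na.rm = TRUE),
    mean_cph_P = mean(.data$cph_P, na.rm = TRUE),
    .groups = "drop")
}

#' Power and robustness study under association models
#'
#' Simulates cohorts under alternative generating models (optionally across
#' several event-age families) and computes per-replicate statistics; summarize
#' with [power_summary()].
#'
#' @param models Model ids (e.g. `c("M2", "M7")`).
#' @param families Generating families.
#' @param n Cohort size.
#' @param n_reps Replicates per model x family.
#' @param statistics Subset of `c("cph", "ppld")`.
#' @param mode `"generating"` to code CPH genotypes under each model's
#'   generating mode of inheritance, or a fixed coding.
#' @param maf Minor allele frequency.
#' @param covariate_law `NULL` for each model's default, else `"fixed"` or
#'   `"random"`.
#' @param base_seed Base seed.
#' @param prior,config PPLD settings.
#' @return Tibble: `model`, `family`, `rep`, `seed`, `cph_P`, `log10br`,
#'   `ppld`.
#' @examples
#' \donttest{
#' pw <- power_study("M2", n_reps = 50, statistics = "cph")
#' power_summary(pw)
#' }
#' @export
power_study <- function(models, families = "MoN", n = 400, n_reps = 1000,
                        statistics = c("cph", "ppld"), mode = "generating",
                        maf = 0.5, covariate_law = NULL, base_seed = 1,
                        prior = trait_prior(), config = ppld_config()) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  grid <- tidyr::expand_grid(model = models, family = families)
  purrr::pmap_dfr(grid, function(model, family) {
    gm <- generating_model(model, family = family, maf = maf,
                           covariate_law = covariate_law)
    cmode <- resolve_mode(mode, gm)
    off <- match(model, names(.model_table)) * 1000L +
      match(family, c("MoN", "WB", "BS", "GM")) * 101L
    purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- replicate_seed(base_seed + off, r)
      coh <- sim_cohort(gm, n, seed = s)
      a <- withr::with_seed(s + 1L,
        analyze_cohort(coh, statistics, cmode, prior, config))
      tibble::tibble(model = model, family = family, rep = r, seed = s,
                     cph_P = a$cph_P, log10br = a$log10br, ppld = a$ppld)
    })
  })
}

#' @rdname power_study
#' @param results Output of [power_study()].
#' @param cph_threshold CPH `-log10(p)` significance threshold (default 5).
#' @param ppld_threshold TE-PPLD threshold (default 0.0201, the empirical
#'   cutoff matched to CPH `P >= 5` under the mixture-of-normals null).
#' @return For `power_summary()`: per model x family, mean (sd) of each
#'   statistic and empirical power with binomial standard errors.
#' @export
power_summary <- function(results, cph_threshold = 5, ppld_threshold = 0.0201) {
  dplyr::summarise(
    dplyr::group_by(results, .data$model, .data$family),
    n_reps = dplyr::n(),
    cph_mean = mean(.data$cph_P, na.rm = TRUE),
    cph_sd = stats::sd(.data$cph_P, na.rm = TRUE),
    cph_power = mean(.data$cph_P >= cph_threshold, na.rm = TRUE),
    cph_power_se = sqrt(.data$cph_power * (1 - .data$cph_power) / .data$n_reps),
    ppld_mean = mean(.data$ppld, na.rm = TRUE),
    ppld_sd = stats::sd(.data$ppld, na.rm = TRUE),
    ppld_power = mean(.data$ppld >= ppld_threshold, na.rm = TRUE),
    ppld_power_se = sqrt(.data$ppld_power * (1 - .data$ppld_power) / .data$n_reps),
    .groups = "drop")
}

#' Epistasis (covariate x genotype interaction) study
#'
#' For each replicate under an interaction model, computes the TE-PPLD three
#' ways -- pooled (covariate-adjusted residuals on the full cohort) and
#' separately within each covariate stratum (subset refit with a single
#' unstratified Weibull) -- together with CPH with and without an interaction
#' term. An interaction is called when the `y = 2` subset TE-PPLD exceeds both
#' the pooled TE-PPLD and the threshold.
#'
#' @param models Interaction model ids (default `"Epi1"`..`"Epi7"`).
#' @param n Cohort size.
#' @param n_reps Replicates per model.
#' @param ppld_threshold Subset TE-PPLD threshold for calling an interaction
#'   (default 0.0430).
#' @param statistics Subset of `c("cph", "ppld")`.
#' @param mode CPH coding (default the generating mode).
#' @param base_seed Base seed.
#' @param prior,config PPLD settings.
#' @return Tibble with one row per model x replicate: `ppld_pooled`,
#'   `ppld_y1`, `ppld_y2`, `cph_P` (no interaction term), `cph_P_gt` and
#'   `cph_P_int` (genotype and interaction terms of the interaction model),
#'   `interaction_called`, `flag`.
#' @export
epistasis_study <- function(models = paste0("Epi", 1:7), n = 400, n_reps = 200,
                            ppld_threshold = 0.0430,
                            statistics = c("cph", "ppld"), mode = "generating",
                            base_seed = 1, prior = trait_prior(),
                            config = ppld_config()) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  purrr::map_dfr(models, function(model) {
    gm <- generating_model(model)
    cmode <- resolve_mode(mode, gm)
    off <- match(model, names(.model_table)) * 977L
    purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- replicate_seed(base_seed + off, r)
      coh <- sim_cohort(gm, n, seed = s)
      row <- tibble::tibble(model = model, rep = r, seed = s,
                            ppld_pooled = NA_real_, ppld_y1 = NA_real_,
                            ppld_y2 = NA_real_, cph_P = NA_real_,
                            cph_P_gt = NA_real_, cph_P_int = NA_real_,
                            interaction_called = NA, flag = "ok")
      withr::with_seed(s + 1L, {
        if ("cph" %in% statistics) {
          f0 <- cph_p(coh, cmode)
          f1 <- cph_p(coh, cmode, interaction = TRUE)
          row$cph_P <- if (f0$degenerate) NA_real_ else f0$P
          row$cph_P_gt <- if (f1$degenerate) NA_real_ else f1$P
          row$cph_P_int <- if (f1$degenerate) NA_real_ else f1$interaction_P
        }
        if ("ppld" %in% statistics) {
          pooled <- tryCatch({
            res <- ote_residuals(coh)
            bayes_ratio(res, coh$genotype, prior, config)$ppld
          }, error = function(e) NA_real_)
          subset_ppld <- function(y) {
            tryCatch({
              sub <- dplyr::filter(coh, .data$covariate == y)
              res <- ote_residuals(sub, stratify = FALSE)
              bayes_ratio(res, sub$genotype, prior, config)$ppld
            }, error = function(e) NA_real_)
          }
          row$ppld_pooled <- pooled
          row$ppld_y1 <- subset_ppld(1)
          row$ppld_y2 <- subset_ppld(2)
          if (anyNA(c(row$ppld_pooled, row$ppld_y1, row$ppld_y2))) {
            row$flag <- "subset_fit_failed"
          } else {
            row$interaction_called <- row$ppld_y2 > row$ppld_pooled &&
              row$ppld_y2 >= ppld_threshold
          }
        }
      })
      row
    })
  })
}

#' Replication versus sequential-updating study
#'
#' Selects an initial "candidate SNP" data set by rejection sampling (the
#' first simulated cohort whose additive CPH `-log10(p)` lands inside
#' `init_cph_band`), then attempts to replicate or confirm it in independent
#' follow-up data sets generated under the association model (`"HA"`) and
#' under the null (`"H0"`). Per follow-up set it records: CPH replication
#' Criterion 1 (the follow-up set alone reaches `P >= 5`), Criterion 2
#' (pooling initial and follow-up reaches `P >= 5`), whether the pooled
#' TE-PPLD exceeds the initial TE-PPLD, and sequential-update success
#' (follow-up Bayes ratio > 1, i.e. follow-up TE-PPLD above the prior).
#'
#' @param model Association model for the initial and `"HA"` follow-up sets.
#' @param n_init,n_rep Initial and follow-up cohort sizes.
#' @param n_reps Follow-up sets per hypothesis.
#' @param init_cph_band Acceptance band for the initial additive CPH `P`.
#' @param statistics Subset of `c("cph", "ppld")`.
#' @param include_pooled Also analyze pooled (initial + follow-up) data sets.
#' @param cph_threshold Replication threshold on `P` (default 5).
#' @param base_seed Base seed.
#' @param max_tries Rejection-sampling cap for the initial data set.
#' @param prior,config PPLD settings.
#' @return A list: `initial` (one-row tibble with the selected data set's
#'   statistics), `replicates` (per follow-up tibble), `summary` (rates per
#'   hypothesis).
#' @export
replication_study <- function(model = "Epi1", n_init = 400, n_rep = 200,
                              n_reps = 1000, init_cph_band = c(5.6, 5.8),
                              statistics = c("cph", "ppld"),
                              include_pooled = TRUE, cph_threshold = 5,
                              base_seed = 1, max_tries = 5000,
                              prior = trait_prior(), config = ppld_config()) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  gm <- generating_model(model, covariate_law = "random")
  gm0 <- generating_model("M1", covariate_law = "random")

  init <- NULL
  for (i in seq_len(max_tries)) {
    s <- replicate_seed(base_seed + 7654321L, i)
    coh <- sim_cohort(gm, n_init, seed = s)
    fit <- cph_p(coh, "additive")
    if (!fit$degenerate && fit$P >= init_cph_band[1] &&
        fit$P <= init_cph_band[2]) {
      init <- list(cohort = coh, cph_P = fit$P, seed = s, tries = i)
      break
    }
  }
  if (is.null(init)) {
    stop("no initial data set found in ", max_tries, " tries for band [",
         init_cph_band[1], ", ", init_cph_band[2], "]", call. = FALSE)
  }
  init_ppld <- NA_real_
  if ("ppld" %in% statistics) {
    res <- ote_residuals(init$cohort)
    b <- withr::with_seed(init$seed + 1L,
      bayes_ratio(res, init$cohort$genotype, prior, config))
    init_ppld <- b$ppld
  }
  initial <- tibble::tibble(model = model, n = n_init, seed = init$seed,
                            tries = init$tries, cph_P = init$cph_P,
                            ppld = init_ppld)

  run_one <- function(hyp, r) {
    m <- if (hyp == "HA") gm else gm0
    s <- replicate_seed(base_seed + ifelse(hyp == "HA", 11L, 13L) * 1e5, r)
    coh <- sim_cohort(m, n_rep, seed = s)
    out <- tibble::tibble(hypothesis = hyp, rep = r, seed = s,
                          cph_P_rep = NA_real_, cph_P_pooled = NA_real_,
                          br_rep = NA_real_, ppld_rep = NA_real_,
                          ppld_pooled = NA_real_)
    withr::with_seed(s + 1L, {
      if ("cph" %in% statistics) {
        f <- cph_p(coh, "additive")
        out$cph_P_rep <- if (f$degenerate) NA_real_ else f$P
        if (include_pooled) {
          pooled <- dplyr::bind_rows(init$cohort, coh)
          fp <- cph_p(pooled, "additive")
          out$cph_P_pooled <- if (fp$degenerate) NA_real_ else fp$P
        }
      }
      if ("ppld" %in% statistics) {
        b <- tryCatch({
          res <- ote_residuals(coh)
          bayes_ratio(res, coh$genotype, prior, config)
        }, error = function(e) NULL)
        if (!is.null(b)) {
          out$br_rep <- b$br
          out$ppld_rep <- b$ppld
        }
        if (include_pooled) {
          bp <- tryCatch({
            pooled <- dplyr::bind_rows(init$cohort, coh)
            res <- ote_residuals(pooled)
            bayes_ratio(res, pooled$genotype, prior, config)
          }, error = function(e) NULL)
          if (!is.null(bp)) out$ppld_pooled <- bp$ppld
        }
      }
    })
    out
  }
  reps <- purrr::map_dfr(c("HA", "H0"), function(hyp) {
    purrr::map_dfr(seq_len(n_reps), function(r) run_one(hyp, r))
  })
  summary <- dplyr::summarise(
    dplyr::group_by(reps, .data$hypothesis),
    n_reps = dplyr::n(),
    rate_criterion1 = mean(.data$cph_P_rep >= cph_threshold, na.rm = TRUE),
    rate_criterion2 = mean(.data$cph_P_pooled >= cph_threshold, na.rm = TRUE),
    rate_pooled_ppld_gt_init = mean(.data$ppld_pooled > initial$ppld,
                                    na.rm = TRUE),
    rate_br_gt_1 = mean(.data$br_rep > 1, na.rm = TRUE),
    .groups = "drop")
  list(initial = initial, replicates = reps, summary = summary)
}

#' Scaled genome-scan mimic
#'
#' Simulates an initial scan of independent SNPs -- `n_null` generated under
#' the null and one per association model -- each as an independent cohort
#' with its own array-like MAF and random covariate proportion, analyzed with
#' additive CPH and the TE-PPLD. Candidate SNPs crossing each threshold are
#' followed up in an independent smaller data set generated under the same
#' model and MAF: CPH replication requires the follow-up or the pooled
#' analysis to reach `P >= 5`; TE-PPLD confirmation requires the follow-up
#' Bayes ratio to exceed 1 (sequential updating increases the PPLD).
#'
#' @param n_null Number of null SNPs (the full-scale experiment used 1e6;
#'   default scaled down).
#' @param assoc_models Association model ids, one SNP each.
#' @param n_init,n_rep Initial and follow-up cohort sizes.
#' @param cph_thresholds,ppld_thresholds Candidate-selection thresholds.
#' @param cph_replication_threshold Follow-up threshold on `P`.
#' @param base_seed Base seed.
#' @param prior,config PPLD settings (a smaller `n_points` is adequate here).
#' @return A list of class `te_genome_scan`: `snps` (per-SNP tibble with
#'   `truth`, `model`, `maf`, `cph_P`, `ppld`, follow-up columns), `counts`
#'   (true/false positives and replications/confirmations per statistic x
#'   threshold), `ranks` (rank of each association SNP under both statistics).
#' @export
genome_scan_experiment <- function(n_null = 1000,
                                   assoc_models = names(.model_table)[-1],
                                   n_init = 400, n_rep = 200,
                                   cph_thresholds = c(5, 7.3),
                                   ppld_thresholds = c(0.0430, 0.10, 0.40),
                                   cph_replication_threshold = 5,
                                   base_seed = 1, prior = trait_prior(),
                                   config = ppld_config(n_points = 1024)) {
  n_snps <- n_null + length(assoc_models)
  mafs <- withr::with_seed(replicate_seed(base_seed, 999983L),
                           sample_chip_maf(n_snps))
  models <- c(rep("M1", n_null), assoc_models)

  snps <- purrr::map_dfr(seq_len(n_snps), function(i) {
    gm <- generating_model(models[i], maf = mafs[i], covariate_law = "random")
    s <- replicate_seed(base_seed + 17L, i)
    coh <- sim_cohort(gm, n_init, seed = s)
    withr::with_seed(s + 1L, {
      f <- cph_p(coh, "additive")
      res <- ote_residuals(coh)
      b <- bayes_ratio(res, coh$genotype, prior, config)
    })
    tibble::tibble(snp_id = sprintf("snp%05d", i),
                   truth = ifelse(models[i] == "M1", "H0", "HA"),
                   model = models[i], maf = mafs[i],
                   cph_P = ifelse(f$degenerate, NA_real_, f$P),
                   br = b$br, log10br = b$log10br, ppld = b$ppld)
  })

  # follow-up for every SNP crossing any threshold (computed once per SNP)
  cand <- which(
    snps$ppld >= min(ppld_thresholds) |
      (!is.na(snps$cph_P) & snps$cph_P >= min(cph_thresholds)))
  follow <- purrr::map_dfr(cand, function(i) {
    gm <- generating_model(snps$model[i], maf = snps$maf[i],
                           covariate_law = "random")
    s <- replicate_seed(base_seed + 29L, i)
    coh <- sim_cohort(gm, n_rep, seed = s)
    withr::with_seed(s + 1L, {
      f <- cph_p(coh, "additive")
      res <- ote_residuals(coh)
      b <- bayes_ratio(res, coh$genotype, prior, config)
      pooled <- dplyr::bind_rows(
        sim_cohort(gm, n_init, seed = replicate_seed(base_seed + 17L, i)), coh)
      fp <- cph_p(pooled, "additive")
    })
    tibble::tibble(snp_id = snps$snp_id[i],
                   rep_cph_P = ifelse(f$degenerate, NA_real_, f$P),
                   pooled_cph_P = ifelse(fp$degenerate, NA_real_, fp$P),
                   rep_br = b$br)
  })
  snps <- dplyr::left_join(snps, follow, by = "snp_id")
  snps$cph_replicated <- !is.na(snps$rep_cph_P) &
    (snps$rep_cph_P >= cph_replication_threshold |
       (!is.na(snps$pooled_cph_P) &
          snps$pooled_cph_P >= cph_replication_threshold))
  snps$ppld_confirmed <- !is.na(snps$rep_br) & snps$rep_br > 1

  count_block <- function(stat, thr) {
    sel <- if (stat == "cph") {
      !is.na(snps$cph_P) & snps$cph_P >= thr
    } else {
      snps$ppld >= thr
    }
    tp <- sum(sel & snps$truth == "HA")
    fp <- sum(sel & snps$truth == "H0")
    conf <- if (stat == "cph") snps$cph_replicated else snps$ppld_confirmed
    tibble::tibble(statistic = stat, threshold = thr,
                   n_true_positive = tp, n_false_positive = fp,
                   tpr = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
                   n_true_confirmed = sum(sel & conf & snps$truth == "HA"),
                   n_false_confirmed = sum(sel & conf & snps$truth == "H0"))
  }
  counts <- dplyr::bind_rows(
    purrr::map_dfr(cph_thresholds, function(th) count_block("cph", th)),
    purrr::map_dfr(ppld_thresholds, function(th) count_block("ppld", th)))

  ranks <- dplyr::mutate(
    dplyr::arrange(
      dplyr::select(
        dplyr::mutate(snps,
                      rank_ppld = rank(-.data$ppld, ties.method = "min"),
                      rank_cph = rank(-dplyr::coalesce(.data$cph_P, -Inf),
                                      ties.method = "min")),
        "snp_id", "truth", "model", "rank_ppld", "rank_cph"),
      .data$rank_ppld),
    truth = NULL)
  ranks <- ranks[ranks$model != "M1", ]

  structure(list(snps = snps, counts = counts, ranks = ranks),
            class = "te_genome_scan")
}

#' @export
print.te_genome_scan <- function(x, ...) {
  cat("<te_genome_scan> ", nrow(x$snps), "SNPs (",
      sum(x$snps$truth == "HA"), "associated )\n")
  print(x$counts)
  invisible(x)
}
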