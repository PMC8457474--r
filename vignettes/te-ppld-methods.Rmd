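---
title: "TE-PPLD methods: model, residuals, quadrature and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TE-PPLD methods: model, residuals, quadrature and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(teppld)
```

This vignette documents the statistical model behind the package, the
numerical choices it makes, what the synthetic-data generator does and does
not emulate, and the known limitations. It is the place where design
decisions that were genuinely open are written down.

## The evidence model

The package measures evidence for SNP–trait association with a quantitative
phenotype through a Bayes ratio,

$$\mathrm{BR} = \int \mathrm{LR}(\gamma)\, f(\gamma)\, d\gamma, \qquad
\mathrm{LR}(\gamma) = \prod_i
\frac{\phi(t_i;\, \mu_{g_i}, \sigma_{g_i})}
     {\sum_g P(g)\, \phi(t_i;\, \mu_g, \sigma_g)},$$

where $\gamma = (\mu_{11}, \mu_{12}, \mu_{22}, \sigma_{11}, \sigma_{12},
\sigma_{22})$ are genotype-specific normal means and SDs of the phenotype and
$P(g)$ are Hardy–Weinberg genotype frequencies at the sample allele
frequency. Because all six parameters are integrated over, recessive,
additive, dominant and variance-only genotype effects are covered by one
analysis: no mode of inheritance is specified. The likelihood is implemented
only in this reduced form; the recombination fraction (0), the standardized
LD parameter $D'$ (1) and the admixture parameter (1) are stored constants
whose fixed values collapse the general trait–marker LD likelihood so that
the trait-locus genotype coincides with the observed SNP genotype. The ratio
is integrated *as a unit* (one integral of the ratio, not a ratio of two
integrals), which preserves the conditional-on-trait ascertainment
correction.

The PPLD rescales the Bayes ratio onto $(0, 1)$:
$\mathrm{PPLD} = \pi\,\mathrm{BR} / (\pi\,\mathrm{BR} + 1 - \pi)$ with
$\pi = 0.0004$, the prior probability that a random SNP sits in detectable
LD of a trait locus. PPLD $> \pi$ is evidence for association, $< \pi$
evidence against; the transform is exact algebra, tested as such. Evidence
from independent cohorts multiplies on the BR scale (`sequential_update()`),
the Bayesian replacement for replication p-value criteria.

**Assumptions.** Unrelated individuals; a biallelic SNP analyzed marginally;
genotype-conditional normality of the (residual) phenotype. Robustness to
violations of the normality assumption is exactly what the Weibull /
Birnbaum–Saunders / Gamma arms of the simulation studies probe.

## OTE residuals for censored phenotypes

Covariates are adjusted once per cohort, independently of genotype, by
converting the censored phenotype into ordinary time-to-event residuals:

1. fit a 2-parameter Weibull per covariate stratum by censored maximum
   likelihood (density terms for events, survival terms for censored
   observations); the fit is delegated to `survival::survreg()`, the
   field-standard censored-Weibull MLE, and reparameterized to shape/scale;
2. residual of an event individual: $t_i - \hat\mu_y$, with $\hat\mu_y =
   \hat\lambda_y\,\Gamma(1 + 1/\hat k_y)$ the stratum Weibull mean;
3. residual of a censored individual: $E[T \mid T > t_i] - \hat\mu_y$ under
   the stratum fit, computed through the regularized upper incomplete gamma
   function, which is always at least $t_i - \hat\mu_y$;
4. residuals are pooled across strata and standardized to mean 0, sd 1, the
   scale the trait-model prior box assumes.

This keeps the scale and interpretation of an ordinary regression residual,
which martingale or deviance residuals do not. When a data set is subset to
a single covariate level (the epistasis analyses), a single pooled fit is
used instead of stratified fits, so no information leaks across strata. If
the survival probability at a censoring time underflows, the conditional
mean saturates at the censoring time itself (documented, tested).

One consequence worth knowing: conditional-mean imputation is deterministic,
so heavily censored strata lose some within-genotype dispersion. This
attenuates variance-only genotype effects relative to mean effects (see
*Calibration* below).

## Prior and quadrature

The prior $f(\gamma)$ is a product of independent uniforms: each mean on
$[-3, 3]$ and each SD on $[0.3, 3]$ in standardized-residual units, with no
ordering constraint. A means-only mode collapses the three SDs to one shared
dimension (and a degenerate SD interval pins it completely). These ranges
comfortably contain any plausible standardized genotype model while keeping
the null-evidence behavior (PPLD mass moving below $\pi$ as $N$ grows).

The integral is evaluated by a deterministic quasi-random rule rather than a
tensor product grid, and the reason is the shape of the integrand. At
cohort sizes of a few hundred, $\mathrm{LR}(\gamma)$ has (i) a data-driven
peak of width $\mathcal{O}(n^{-1/2}) \approx 0.1$ — far too narrow for any
coarse fixed grid on a box of width 6 — and (ii) a diffuse high-volume
region (large SDs, where the association and mixture models almost coincide)
that carries most of the remaining mass. The rule therefore evaluates the
log likelihood ratio at `n_points` (default 4096) Halton-sequence points
split three ways: 60% mapped uniformly over the box (the diffuse mass), 20%
through wide and 20% through narrow truncated-normal transforms centered at
the integrand mode, which is located per SNP by a Nelder–Mead search started
at the genotype-group moments, with component widths taken from the
numerical Hessian (floored and capped). The estimate is the defensive
importance-sampling average with the exact mixture density, assembled in log
space (log-sum-exp) so that Bayes ratios of $10^{\pm 300}$ are handled
without under- or overflow.

Properties of this rule, all under test:

* it is bit-reproducible given `n_points` (no RNG is consumed);
* on small instances ($n \le 20$) it agrees with a brute-force Monte-Carlo
  prior average within Monte-Carlo error;
* a monomorphic SNP short-circuits to $\mathrm{BR} = 1$ exactly
  (evidence-neutral, unlike the comparator's undefined fit);
* relabeling the alleles ($g \to 2 - g$) gives the identical result, because
  genotypes are canonicalized to minor-allele counts before integration;
* a split-half error estimate (`log10br_se`, in log10 units) is reported per
  SNP and flagged against a tolerance (default 1.0) instead of being
  silently accepted. Strong signals are peak-dominated and very stable
  (±0.01 log10 across point budgets); weak-to-moderate signals carry more
  quadrature noise (up to ±0.2 log10 at the default budget), which matters
  little after the PPLD transform.

`n_points` trades time for accuracy linearly; 1024 is adequate for ranking
in large scans, 4096 (default) for reported PPLDs, 8192+ for tight log10 BR
comparisons.

## The synthetic-data generator

`generating_model()` encodes the study conditions: a null model, seven
baseline association models (additive, wider-variance, dominant, recessive,
mean+variance, variance-only, covariate-dependent), and seven
covariate-by-genotype interaction ("epistasis") models, all specified on a
standard-normal scale per genotype × covariate cell. The years mapping is
anchored at a mean of 11.6 y and SD of 3.4 y — the uncensored,
untreated-stratum loss-of-ambulation moments the models are calibrated to —
via $t = 11.6 + 3.4 z$, with 3 years added to the level-2 covariate means
(except the one model whose level-2 cells are explicit). Event-age
distributions are truncated normals (inverse-CDF sampling on the
renormalized distribution, for reproducibility; truncation at 0 is a
>3-sigma event and numerically negligible, so the 3-year offset is applied
on the untruncated scale), or Weibull / Birnbaum–Saunders / Gamma members
matched to each cell's untruncated years-scale mean and SD — Gamma in closed
form, the other two by solving the coefficient-of-variation equation to
relative error below 1e-9.

Observation (censoring) ages are negative-binomial counts of failures before
the 10th success with success probability 0.4 — mean 15 y — with zero draws
redrawn; this is the one common NB parameterization whose arithmetic
reproduces the intended ≈40% censoring rate against event ages averaging
≈13 y (the realized rate under the null model is just under 42%, computed
by the acceptance script). Covariates are assigned either exactly half and
half, or with a per-replicate level-2 proportion drawn from
Normal(0.7, 0.1) truncated to (0, 1) followed by independent Bernoulli
assignment (the replicate-to-replicate variability that drives the
replication analyses). Genotypes are Hardy–Weinberg draws at the model MAF;
a genome-scan MAF spectrum is emulated by a Beta distribution rescaled to
(0.03, 0.5) with mean 0.23 and SD 0.14, matching a common-variant array
after a 3% MAF filter.

**What the generator does not emulate:** linkage disequilibrium between
SNPs (scan SNPs are independent), related individuals, population
stratification, genotyping error or missingness, informative censoring, and
real LOA-distribution features beyond two moments. Tests passing on these
cohorts therefore validate the statistical machinery under the stated
conditions, not performance on any particular real data set.

Every replicate of every study runs under a child seed derived
deterministically from `(base_seed, replicate)`, so studies are
bit-reproducible and resumable.

## Numerical and design choices at open points

* **Threshold order statistic.** Empirical thresholds are the k-th largest
  statistic; ties at the boundary count as above-or-equal (`>=` in all
  power/count rules).
* **Degenerate comparator fits.** A constant coded predictor (e.g. no minor
  homozygote under recessive coding), a failed fit or a non-finite
  coefficient yields a flagged degenerate row, never an error; this mirrors
  the NaN behavior of standard software that motivates the comparison.
  Quasi-separated recessive fits at low MAF converge with finite Wald
  statistics and are *kept* — their inflation is part of the phenomenon
  under study.
* **Genotype frequencies.** $P(g)$ uses HWE at the sample-estimated allele
  frequency; user-supplied frequencies are accepted by `log_lr()`.
* **Epistasis subset analyses** refit residuals within each covariate subset
  (single pooled Weibull there), avoiding any cross-stratum information
  leak; the interaction call requires the level-2 subset PPLD to exceed
  both the pooled PPLD and a threshold.
* **Replication candidates** are selected by rejection sampling into a band
  of initial Cox P values, mirroring follow-up of a specific observed
  signal.
* **Configuration** is by function arguments (tibble-in/tibble-out,
  pipe-friendly) rather than config files; the CLI under `inst/cli/` wraps
  the four pipeline steps for shell use.

## Problem sizes

The test suite runs the studies at desk scale, chosen to keep the full suite
under a coffee break on one CPU while leaving every comparison inside
3-standard-error bands at the replicate counts actually run: 300–400
replicates for Cox sampling summaries, 150–200 cohorts per TE-PPLD
condition, 1,000 cohorts for the censoring calibration, 15,000–30,000
replicates for the low-MAF tail rates, and a 134-SNP genome-scan mimic. The
acceptance script uses 1,000 replicates for Cox-side quantities, 200 for
TE-PPLD-side ones, and estimates the two per-million tail counts at
$10^5$–$10^6$ replicates.

## Known limitations

* The prior over $\gamma$ is this package's own choice. The PPLD literature
  does not publish the reference implementation's prior ranges or quadrature
  tolerances, and absolute PPLD values are prior-dependent: published
  empirical thresholds (e.g. 0.0201) were calibrated against *that*
  implementation's null distribution. This package's null distribution is
  more conservative, so power read at a fixed published threshold can
  differ from published power even when rankings and qualitative behavior
  agree; mean-effect models land close, variance-only models read several
  points lower. For decision-making with this package, calibrate thresholds
  against its own null via `null_study()` + `threshold_top_k()`.
* Deterministic conditional-mean residuals attenuate variance signals under
  heavy censoring (see above).
* Pedigrees and related individuals are out of scope; so are $\theta > 0$,
  $D' < 1$, a free admixture parameter, dosage genotypes and binary PLINK /
  BGEN formats.
* Single-replicate genome-scan tables are luck-of-the-draw by construction;
  only structural properties (matched-threshold false-positive parity under
  the null, top-ranking of strong signals) are reproducible and tested.
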