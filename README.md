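# teppld

Bayesian evidence measures for SNP–trait association with **censored
time-to-event phenotypes** in small to moderate GWAS cohorts, together with
the Cox proportional-hazards comparator and a full simulation-evaluation
framework.

The motivating setting is a modifier-gene GWAS for a rare Mendelian disorder
(age at loss of ambulation in Duchenne muscular dystrophy), where cohorts of
N ≈ 200–800 are the realistic ceiling and conventional p-value machinery
behaves poorly: p-value distributions under the null do not improve with
sample size, recessive regression tests inflate badly at low minor-allele
frequency, and independent replication at these sample sizes is mostly a coin
flip. The TE-PPLD addresses this by measuring evidence for *and against*
association on a posterior-probability scale.

## The statistic

For one SNP with genotypes g ∈ {0,1,2} (minor-allele counts) and a
quantitative phenotype t, the **Bayes ratio** integrates the
association/no-association likelihood ratio over the trait-model parameters
γ = (μ₁₁, μ₁₂, μ₂₂, σ₁₁, σ₁₂, σ₂₂) — three genotype-specific normal means
and SDs, so no mode of inheritance is ever specified:

    BR = ∫ LR(γ) f(γ) dγ,
    LR(γ) = Π_i  φ(t_i; μ_{g_i}, σ_{g_i}) / Σ_g P(g) φ(t_i; μ_g, σ_g)

with P(g) the Hardy–Weinberg genotype frequencies at the sample allele
frequency (recombination fraction θ = 0, D′ = 1 and admixture 1 collapse the
general trait–marker LD likelihood onto this reduced form). The **PPLD**
rescales the Bayes ratio by the prior probability π = 0.0004 that a random
SNP is in detectable LD with a trait locus:

    PPLD = π·BR / (π·BR + 1 − π)

PPLD > π is evidence for association, PPLD < π evidence against. Evidence
accumulates across data sets by multiplying BRs (sequential updating).

Censored event ages enter through **ordinary time-to-event (OTE) residuals**:
a two-parameter Weibull is fit per covariate stratum by censored maximum
likelihood; an individual's residual is the observed event age (events) or
the conditional mean event age beyond the censoring time (censored) minus the
stratum Weibull mean. The residuals keep the years scale and the usual
"how unusual is this individual given covariates" reading, and are
standardized before entering the Bayes ratio.

The comparator, `cph_p()`, is Cox proportional-hazards regression of
(time, event) on a coded genotype plus the covariate, reported as
P = −log₁₀ of the genotype Wald p (Efron ties, via the survival package).

## Worked example

```r
library(teppld)

model <- generating_model("M2")            # additive effect, MAF 0.5
cohort <- sim_cohort(model, n = 400, seed = 1)
mean(cohort$event == 0)
#> [1] 0.4925                               # ~40–50% censored by design

res <- ote_residuals(cohort)               # stratified Weibull OTE residuals

cph_p(cohort)                              # Cox comparator
#>   coefficient    p_value     P coding   degenerate
#>        -0.499 0.00000382  5.42 additive FALSE

bayes_ratio(res, cohort$genotype)          # TE-PPLD
#>      br log10br  ppld n_used maf_hat n_eval log10br_se flag
#>   4115.    3.61 0.622    400   0.491   4096      0.321 ok

sequential_update(c(4115, 2.4))            # confirm in a second data set
#>      br log10br  ppld n_datasets
#>   9876.    3.99 0.798          2
```

Here both statistics detect the simulated association: the Cox test reaches
P = 5.42 and the TE-PPLD reaches 0.62 — a 62% posterior probability of
association, well above the 10%/40% follow-up heuristics. A follow-up data
set with BR = 2.4 (> 1, i.e. supporting association on its own) raises the
updated PPLD to 0.80.

The evaluation studies are one call each: `null_study()` (sampling
distributions under no association), `power_study()` + `power_summary()`
(power and robustness across mixture-of-normals, Weibull, Birnbaum–Saunders
and Gamma event-age families), `epistasis_study()` (pooled versus
covariate-stratified analysis), `replication_study()` (replication criteria
versus sequential updating) and `genome_scan_experiment()` (a scaled
genome-scan mimic). A thin command-line wrapper with `simulate`,
`residuals`, `ppld` and `cph` subcommands lives in `inst/cli/te-ppld.R`.

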