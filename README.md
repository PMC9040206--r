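# riskstrat

Tools for comparing four breast-cancer risk-stratification criteria on a
common cohort:

1. **Family history (FH)** — a first-degree relative with breast or
   ovarian cancer;
2. **Gail model** — 5-year absolute risk ≥ 1.3% from questionnaire risk
   factors (BCRAT-style, with Asian-American "AABCS" coefficients bundled);
3. **Polygenic risk score (PRS)** — 5-year absolute risk ≥ 1.3% from a
   313-variant score;
4. **PTV carriership** — a protein-truncating variant (nonsense,
   frameshift, or splice-disrupting; last-exon variants excluded as
   NMD-escaping) in *ATM*, *BRCA1*, *BRCA2*, *CHEK2*, *PALB2*, *BARD1*,
   *RAD51C*, *RAD51D*, or *TP53*.

The package is aimed at biostatisticians and genetic-epidemiology groups
evaluating risk-stratified screening: it computes each criterion,
quantifies how (dis)similarly they classify the same women — pairwise
Cohen's kappa, Spearman correlation and Wilcoxon signed-rank between the
two absolute risks, a full Venn decomposition, and incremental
identification by 5-year age group — and ships a synthetic-cohort
generator so the whole pipeline runs end to end without access to
restricted patient data.

## The model in brief

Absolute risks are 5-year cumulative incidences under piecewise-constant
hazards with competing mortality:

```
AR₅(a) = ∫ₐ^{a+5} h(t) · exp(−∫ₐᵗ [h(u) + m(u)] du) dt
```

For the PRS, h(t, z) = h₀(t)·exp(βz) with z the standardized score; h₀ is
calibrated iteratively against registry incidence while the survivor PRS
distribution (held on Gauss–Hermite quadrature nodes) is depleted interval
by interval, so that population incidence is conserved exactly.  For the
Gail model, h(t) = RR(profile, t) × incidence(t) × (1 − AR(t)), with the
relative risk and attributable risk switching at age 50.  The 1.3%
threshold is the 5-year risk of an average-risk US white woman at age 50,
which the bundled reference rates reproduce (1.298%).

See the methods vignette
(`vignettes/risk-stratification-methods.Rmd`) for assumptions, parameter
defaults and numerical choices.

## Worked example

```r
library(riskstrat)

cfg <- pipeline_config(
  simulation = sim_config(n_individuals = 7600, seed = 2026),
  seed = 2026, output_dir = "report")
res <- run_pipeline(cfg)

res$risk_comparison
#>              statistic     value
#> 1         spearman_rho  2.46e-01
#> 2           wilcoxon_p  1.82e-50
#> 3  median_prs_risk_pct  8.74e-01
#> 4 median_gail_risk_pct  9.95e-01
#> 5      median_diff_pct -9.81e-02

head(res$kappa, 2)
#>   criterion_a criterion_b   kappa  p_value status
#> 1          FH        Gail 0.48457 0.00e+00     ok
#> 2          FH         PRS -0.00701 5.35e-01    ok

sum(res$classification$any_high)
#> [1] 3622
res$venn$marginals
#>   FH Gail  PRS  PTV
#> 1279 1985 1684  365
```

On this synthetic series of 7,600 diagnoses, 48% are flagged by at least
one criterion; the PRS and Gail 5-year risks correlate only weakly
(Spearman ρ = 0.25) and differ systematically (median difference −0.098
percentage points, signed-rank p ≪ 0.001); the only substantial pairwise
agreement is FH with the Gail model (κ = 0.48), expected because family
history is itself a Gail input.  The `report/` directory receives the full
set of TSV tables (cohort summary, per-individual classification, kappa
matrix, 16-region Venn counts for the whole cohort and the under-50
subset, incremental age table) plus a resolved-config echo and run log.

A thin command-line front end with `run`/`simulate`/`score`/`risk`/
`classify` subcommands is installed at
`system.file("scripts", "riskstrat.R", package = "riskstrat")`.

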