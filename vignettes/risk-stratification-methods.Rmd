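---
title: "Methods: four-way breast cancer risk stratification on synthetic cohorts"
author: "riskstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-way breast cancer risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskstrat)
```

## The problem

Risk-stratified breast-cancer screening asks which women warrant earlier or
more intensive screening.  Four criteria are in common use, each capturing a
different component of risk:

1. **Family history (FH)** — at least one first-degree relative with breast
   or ovarian cancer;
2. **Gail-model risk** — a 5-year absolute risk at or above a threshold,
   computed from questionnaire factors (age at menarche, age at first live
   birth, breast biopsies, family history);
3. **PRS risk** — the same absolute-risk threshold applied to a
   313-variant polygenic risk score;
4. **PTV carriership** — a protein-truncating variant in one of nine
   predisposition genes (*ATM*, *BRCA1*, *BRCA2*, *CHEK2*, *PALB2*,
   *BARD1*, *RAD51C*, *RAD51D*, *TP53*).

These criteria select substantially different women.  `riskstrat`
implements each criterion and the machinery to quantify their overlap and
concordance (Cohen's kappa, Spearman correlation, Wilcoxon signed-rank,
Venn decomposition, incremental identification by age group), and — because
the patient-level data that motivate such analyses are restricted — a
synthetic-cohort generator so the entire pipeline is exercised end to end
by code alone.

The conventional threshold of **1.3%** is the 5-year absolute risk of an
average-risk US white woman at age 50, the usual screening entry age; the
package reproduces this anchor from its bundled reference rates
(`threshold_reference_risk()` returns
`r sprintf("%.3f%%", 100 * threshold_reference_risk(load_rates(system.file("extdata", "us_white_rates.csv", package = "riskstrat"))))`).

## Absolute risk with competing mortality

All absolute risks are 5-year cumulative incidences under piecewise-constant
hazards.  Given a breast-cancer hazard $h(t)$ and a competing
(non-breast-cancer death) hazard $m(t)$, both constant on 5-year age
intervals as registries publish them,

$$
AR_5(a) \;=\; \int_a^{a+5} h(t)\,
  \exp\!\Big(-\!\int_a^t \big[h(u) + m(u)\big]\,du\Big)\,dt ,
$$

evaluated in closed form per sub-interval:
$\frac{h}{h+m}\big(1 - e^{-(h+m)\Delta}\big)$ weighted by survival to the
sub-interval's start.  Windows that start off a 5-year boundary are split at
boundary crossings; rates are never interpolated, matching the resolution
at which they are recorded.  The competing-mortality column is taken as
supplied (ideally all-cause mortality minus breast-cancer-specific deaths;
the bundled tables already carry a competing-mortality column).

### PRS calibration

The PRS model is proportional hazards on the standardized score
$z$: $h(t, z) = h_0(t)\,e^{\beta z}$ with $\beta$ the per-SD log relative
risk.  A naive choice $h_0 = \lambda$ (the registry incidence) would
overstate population incidence, because averaging $e^{\beta z}$ over a
standard-normal population gives $e^{\beta^2/2} > 1$ — and because women
with high $z$ are diagnosed earlier and leave the at-risk pool, the
survivor PRS distribution drifts downward with age.  The calibration
therefore proceeds iteratively from the youngest interval:

* the survivor distribution of $z$ (initially standard normal, represented
  on Gauss–Hermite quadrature nodes) fixes
  $h_0(t) = \lambda(t) / E_{\mathrm{surv}}[e^{\beta z}]$;
* survivor weights are then depleted by each node's interval hazard,
  $w \leftarrow w\,e^{-\Delta\,h_0 e^{\beta z}}$, and renormalized.
  Competing mortality is independent of $z$ and cancels in the
  renormalization.

By construction the survivor-averaged incidence reproduces the input table
(the test suite checks conservation to $10^{-6}$ relative error for
$\beta \in [0, 1.2]$, and agreement of the 64-node quadrature with a
$10^5$-point grid to $10^{-8}$).

$\beta$ is a configuration input.  Its default, $\log 1.61 \approx 0.476$,
is the per-SD odds ratio widely reported for the 313-variant breast-cancer
PRS; analyses of specific populations should substitute their own estimate.

### Gail projection

The Gail (BCRAT-style) relative risk is
$RR = \exp(\sum_k c_k x_k)$ over coded categories of menarche age, age at
first live birth, biopsy history and number of affected first-degree
relatives (binary here, as questionnaires often record it), with the
biopsy-by-age and first-birth-by-relatives interactions evaluated per age
segment ($<50$, $\ge 50$).  Unknown categories fall to the reference
(lowest-risk) class, the convention of the standard tooling.  The absolute
risk multiplies $RR$ by a baseline hazard obtained from composite
incidence times $1 - AR$ (attributable risk) of the applicable segment;
both $RR$ and $AR$ are re-evaluated when a projection window crosses age
50.  The bundled parameter file carries the published Asian-American
(AABCS) coefficients and attributable risks; it is plain text, so other
populations' parameters can be swapped in without code changes.

Setting all coefficients and $AR$ to zero (`gail_params_null()`) reduces
the projection to the population-average risk — the parameterization under
which the age-50 threshold anchor above is computed.

### PTV classification

Carriership is rule-based on annotated variant records: a qualifying
variant is a nonsense SNV, frameshift indel, or splice-disrupting SNV in a
panel gene, *excluding* variants in the gene's last exon, which typically
escape nonsense-mediated decay and may not abolish protein function.  The
last-exon exclusion is applied to all three truncating classes.  No
pathogenicity scoring is attempted; the classifier consumes upstream
annotations.

## The synthetic cohort

`simulate_cohort()` emulates a case series of women diagnosed between ages
30 and 75:

* **Ages**: truncated normal, mean 52, SD 10.4, truncated to [30, 75] —
  median 52 with IQR ≈ 45–59, typical of Asian case series.
* **Risk factors**: drawn independently from category maps whose defaults
  match such a series — menarche 29/52/11/8% (≥14, 12–13, <12, unknown),
  first birth 4/19/30/24/17/5% (<20, 20–25, 25–30, ≥30, nulliparous,
  unknown), breast-cancer family history 15%, ovarian 2%, PTV carriership
  5%.  Ever-biopsy is not tabulated in the series these defaults mirror;
  10% was chosen as a plausible prevalence for Asian populations with
  historically lower screening uptake.  Unknown categories are generated
  explicitly so downstream unknown-handling is exercised.
* **Genotypes**: Hardy–Weinberg dosages at the bundled synthetic
  313-variant panel (frequencies drawn once from a Beta-shaped MAF
  distribution; weights ~N(0, 0.06²)).  The panel is synthetic — its ids,
  alleles and weights do not correspond to any published PRS.
* **Case sampling**: `sample_cases_by_risk()` draws cases without
  replacement with probability proportional to $e^{\beta z}$ (the
  rare-disease log-linear model), under which cases from an N(0,1)
  population are N($\beta$, 1).  Sampling uses exponential-key weighted
  reservoir selection, which is exact and scales to millions of
  individuals.  Note that at sampling fractions above a few percent the
  without-replacement depletion visibly attenuates the realized shift
  (≈0.02 at a 5% fraction for $\beta = 0.6$); parameter-recovery analyses
  should keep the case fraction small, as real incidences are.

What the generator does **not** model: joint structure among risk factors
(real FH correlates with PTV carriership and with Gail risk by
construction), linkage disequilibrium between variants, age-dependent
risk-factor distributions, and secular changes in rates.  Passing tests on
synthetic cohorts therefore demonstrate the correctness of the machinery,
not the cohort-dependent headline proportions of any real population.

## Numerical choices

* Quadrature: 64 Gauss–Hermite nodes by default; the per-interval
  fixed-point refinement stops at relative change $10^{-10}$.
* Threshold comparison is **inclusive** (`risk ≥ threshold`), with a
  strict mode available; reported counts in the motivating analyses use
  the inclusive convention.
* Kappa p-values use the large-sample null standard error
  (Fleiss–Cohen–Everitt); a degenerate table ($p_e = 1$) is reported as an
  explicit status, not a number.
* Signed-rank: zeros dropped before ranking (classical convention — at
  small n results are sensitive to this choice); exact null for ≤25
  untied nonzero differences, tie-corrected normal approximation
  otherwise.
* Missing genotypes default to mean imputation ($w_j \cdot 2\hat f_j$ from
  non-missing carriers), matching score-sum tooling defaults; `omit` is
  available.  Allele matching tries the reported orientation, then the
  swap with dosage complement; strand-ambiguous A/T and C/G variants are
  matched as reported and counted in a message, since dosage data carry no
  strand information.
* Age bins for the incremental table are [30, 35) … [70, 75], the last
  closed at 75 to include the oldest eligible diagnosis age.

## Worked example

```{r pipeline}
cfg <- pipeline_config(
  simulation = sim_config(n_individuals = 2000, seed = 11),
  seed = 11, output_dir = file.path(tempdir(), "riskstrat-demo"))
res <- run_pipeline(cfg)
res$risk_comparison
head(res$kappa)
sum(res$classification$any_high) / nrow(res$cohort)
```

The Venn decomposition and the incremental age table:

```{r venn}
subset(res$venn$regions, count > 0)
res$age_table[, 1:4]
```

Typical synthetic-cohort behaviour mirrors the qualitative structure of
real case series — modest rank correlation between PRS and Gail risks,
high kappa only for the FH/Gail pair (the Gail model contains family
history), and incremental proportions that grow most when the PRS
criterion is added — while the exact percentages depend on the configured
marginals and $\beta$.

## Problem sizes

The test suite exercises calibration on 10-interval tables, Monte-Carlo
checks at $10^5$ individuals, parameter recovery at up to $4\times10^6$
population / $5\times10^4$ cases (scores only) and a full pipeline run at
the case-series scale of 7,600; these sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances while keeping a complete
run under a minute on a laptop.

## Known limitations

* The bundled US white-female reference table is of the SEER vintage used
  by the classic Gail implementation; newer vintages shift the age-50
  anchor by a few hundredths of a percentage point.
* Ethnic-specific calibration is supported by loading per-population rate
  tables, but the bundled non-US table is synthetic and labelled as such.
* The Gail model here uses binary family history (0/1 relatives); series
  with relative counts lose information.
* No combined PRS-plus-questionnaire model is provided: the two risks are
  deliberately computed and thresholded separately, since quantifying
  their disagreement is the point.
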