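Package: riskstrat
Title: Breast Cancer Risk Stratification with Polygenic Scores and the Gail Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing breast-cancer risk-stratification criteria:
    polygenic risk score (PRS) based 5-year absolute risk via iterative
    baseline-hazard calibration against age-specific incidence with competing
    mortality, Gail-model (BCRAT-style) 5-year absolute risk with
    Asian-American coefficients, first-degree family history, and
    protein-truncating variant carriership in a nine-gene predisposition
    panel. Includes a synthetic-cohort generator (Hardy-Weinberg genotypes,
    questionnaire risk factors, risk-proportional case sampling), concordance
    statistics (Cohen's kappa, Spearman correlation, Wilcoxon signed-rank,
    Venn overlap decomposition, incremental identification by age group), and
    a configuration-driven pipeline producing the full concordance report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
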