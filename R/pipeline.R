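#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Exactly one of
#' `simulation` (a [sim_config()]) or `cohort_path`+`genotype_path` must be
#' supplied.
#'
#' @param simulation a [sim_config()] describing a synthetic cohort, or NULL.
#' @param cohort_path,genotype_path paths to a cohort TSV ([load_cohort()])
#'   and a dosage matrix TSV or VCF, or NULL.
#' @param weights_path PRS weights TSV; default the bundled synthetic
#'   313-variant panel.
#' @param rates_path rates CSV; default the bundled synthetic Singapore-like
#'   table.
#' @param gail_params_path Gail parameter file; default the bundled
#'   Asian-American (AABCS) parameters.
#' @param threshold high-risk 5-year absolute-risk threshold, in (0, 1).
#' @param beta per-SD log relative risk of the PRS used for calibration and
#'   case sampling.
#' @param n_cases if non-NULL, sample this many cases from the simulated
#'   population proportionally to exp(beta z) and analyse the cases only
#'   (the case-only design).
#' @param young_age_cut age cut for the young-subset overlap report
#'   (default 50, the standard mammography screening entry age).
#' @param quadrature_size Gauss-Hermite size for the hazard calibration.
#' @param seed master seed for every stochastic stage.
#' @param output_dir where [run_pipeline()] writes its report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            cohort_path = NULL, genotype_path = NULL,
                            weights_path = system.file("extdata", "prs313_synthetic.tsv",
                                                       package = "riskstrat"),
                            rates_path = system.file("extdata", "sg_synthetic_rates.csv",
                                                     package = "riskstrat"),
                            gail_params_path = system.file("extdata", "gail_aabcs_params.txt",
                                                           package = "riskstrat"),
                            threshold = 0.013,
                            beta = log(1.61),
                            n_cases = NULL,
                            young_age_cut = 50,
                            quadrature_size = 64L,
                            seed = 1L,
                            output_dir = tempfile("riskstrat_report_")) {
  has_sim <- !is.null(simulation)
  has_paths <- !is.null(cohort_path) || !is.null(genotype_path)
  if (has_sim == has_paths)
    stop("pipeline_config: exactly one of a simulation block or cohort/genotype paths is required")
  if (has_paths && (is.null(cohort_path) || is.null(genotype_path)))
    stop("pipeline_config: both cohort_path and genotype_path are required")
  if (has_sim && !inherits(simulation, "sim_config"))
    stop("pipeline_config: simulation must be a sim_config")
  if (threshold <= 0 || threshold >= 1)
    stop("pipeline_config: threshold must be in (0, 1)")
  structure(list(simulation = simulation, cohort_path = cohort_path,
                 genotype_path = genotype_path, weights_path = weights_path,
                 rates_path = rates_path, gail_params_path = gail_params_path,
                 threshold = threshold, beta = beta, n_cases = n_cases,
                 young_age_cut = young_age_cut,
                 quadrature_size = as.integer(quadrature_size),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation:` mapping mirrors [sim_config()] (its `riskfactor_freqs` may
#' override individual maps of [default_riskfactor_freqs()]).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    rf <- default_riskfactor_freqs()
    for (nm in names(s$riskfactor_freqs))
      rf[[nm]] <- unlist(s$riskfactor_freqs[[nm]])
    sim <- sim_config(
      n_individuals = s$n_individuals,
      allele_freqs = if (!is.null(s$allele_freqs)) unlist(s$allele_freqs),
      prs_log_or_per_sd = s$prs_log_or_per_sd %||% log(1.61),
      riskfactor_freqs = rf,
      age_range = unlist(s$age_range %||% c(30, 75)),
      age_mean = s$age_mean %||% 52, age_sd = s$age_sd %||% 10.4,
      missing_rate = s$missing_rate %||% 0,
      seed = s$seed %||% y$seed %||% 1L)
  }
  args <- y[setdiff(names(y), "simulation")]
  args$simulation <- sim
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Table-1-style cohort summary
#'
#' Long-format description: median (IQR) age and risks, and n (%) per
#' category of every categorical field.
#'
#' @param cohort cohort data.frame.
#' @param prs_risk,gail_risk optional aligned 5-year absolute risks.
#' @return Data.frame with columns `variable`, `category`, `n`, `percent`,
#'   `summary`.
#' @export
cohort_summary <- function(cohort, prs_risk = NULL, gail_risk = NULL) {
  n <- nrow(cohort)
  med_iqr <- function(x) {
    if (!length(x) || all(is.na(x))) return("NA")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.1f (%.1f-%.1f)", q[2L], q[1L], q[3L])
  }
  rows <- list(data.frame(variable = "age", category = "median (IQR)",
                          n = n, percent = NA_real_,
                          summary = med_iqr(cohort$age)))
  cat_row <- function(var) {
    x <- cohort[[var]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    tb <- table(factor(x))
    if (!length(tb)) return(NULL)
    data.frame(variable = var, category = names(tb), n = as.integer(tb),
               percent = if (n > 0) round(100 * as.integer(tb) / n, 1)
                         else NA_real_,
               summary = NA_character_)
  }
  for (var in intersect(c("ethnicity", "case_type", "menarche", "first_birth",
                          "biopsy", "fh_breast", "fh_ovarian", "ptv_carrier"),
                        names(cohort)))
    rows[[var]] <- cat_row(var)
  if (!is.null(prs_risk))
    rows$prs <- data.frame(variable = "prs_risk_5y_pct",
                           category = "median (IQR)", n = n,
                           percent = NA_real_,
                           summary = med_iqr(100 * prs_risk))
  if (!is.null(gail_risk))
    rows$gail <- data.frame(variable = "gail_risk_5y_pct",
                            category = "median (IQR)", n = n,
                            percent = NA_real_,
                            summary = med_iqr(100 * gail_risk))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full risk-stratification pipeline
#'
#' Simulates (or ingests) a cohort; computes raw and standardized PRS;
#' optionally samples cases proportionally to exp(beta z); calibrates
#' baseline hazards; projects PRS and Gail 5-year absolute risks; derives
#' PTV carriership from simulated annotated variant records; applies the
#' four high-risk criteria; and writes the concordance report (cohort
#' summary, risk-comparison statistics, kappa matrix, Venn regions for the
#' full cohort and the young subset, incremental age table, per-individual
#' classification).  Fully deterministic under the config seed.
#'
#' @param config a [pipeline_config()].
#' @param write if FALSE, skip writing files and just return the results.
#' @return Invisibly, a list with `cohort`, `scores` (raw, z),
#'   `classification`, `summary`, `risk_comparison`, `kappa`, `venn`,
#'   `venn_young`, `age_table`, `calibration`, `case_mean_z`, `output_dir`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "': ", conditionMessage(e), call. = FALSE))
  }
  weights <- stage("load_weights", load_weights(config$weights_path))
  rates <- stage("load_rates", load_rates(config$rates_path))
  gparams <- stage("load_gail_params", load_gail_params(config$gail_params_path))

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_cohort(config$simulation))
    cohort <- sim$cohort; genotypes <- sim$genotypes
  } else {
    cohort <- stage("load_cohort", load_cohort(config$cohort_path))
    genotypes <- stage("load_genotypes",
      if (grepl("\\.vcf(\\.gz)?$", config$genotype_path))
        load_genotypes_vcf(config$genotype_path)
      else load_dosage_matrix(config$genotype_path))
  }
  n_pop <- nrow(cohort)

  raw <- if (n_pop > 0)
    stage("prs", compute_raw_prs(genotypes, weights)) else numeric(0)
  if (n_pop >= 2 && stats::sd(raw) > 0) {
    ref <- compute_reference_stats(raw, population = "simulated controls")
    z <- standardize_prs(raw, ref)
  } else {
    z <- rep(0, n_pop)
  }

  case_mean_z <- NA_real_
  if (!is.null(config$n_cases)) {
    idx <- stage("sample_cases",
                 sample_cases_by_risk(z, config$beta, config$n_cases,
                                      seed = config$seed + 17L))
    cohort <- cohort[idx, , drop = FALSE]
    z <- z[idx]; raw <- raw[idx]
    case_mean_z <- if (length(z)) mean(z) else NA_real_
  }
  n <- nrow(cohort)

  calib <- stage("calibrate",
                 calibrate_baseline_hazard(rates, config$beta,
                                           config$quadrature_size))
  prs_risk <- if (n > 0)
    stage("prs_risk", prs_absolute_risk(z, cohort$age, calib)) else numeric(0)
  gail_risk <- if (n > 0)
    stage("gail_risk",
          gail_absolute_risk(cohort$menarche, cohort$first_birth,
                             cohort$biopsy, as.integer(cohort$fh_breast),
                             cohort$age, rates, gparams)) else numeric(0)

  variants <- stage("ptv_variants",
                    simulate_ptv_variants(cohort$id, cohort$ptv_carrier,
                                          seed = config$seed + 29L))
  ptv <- stage("ptv", classify_ptv(variants, individual_ids = cohort$id))
  cohort$ptv_carrier <- unname(ptv)

  cls <- stage("classify",
               classify_high_risk(cohort, prs_risk, gail_risk,
                                  threshold = config$threshold))

  flags <- list(FH = cls$fh_high, Gail = cls$gail_high, PRS = cls$prs_high,
                PTV = cls$ptv_carrier)
  venn <- venn_counts(flags)
  young <- cohort$age < config$young_age_cut
  venn_young <- if (any(young)) venn_counts(lapply(flags, `[`, young)) else NULL

  risk_comparison <- if (n >= 3) {
    rho <- rank_correlation(prs_risk, gail_risk)
    wsr <- paired_signed_rank(prs_risk, gail_risk)
    data.frame(
      statistic = c("spearman_rho", "wilcoxon_p", "median_prs_risk_pct",
                    "median_gail_risk_pct", "median_diff_pct"),
      value = c(rho$rho, wsr$p_value,
                stats::median(100 * prs_risk), stats::median(100 * gail_risk),
                stats::median(100 * (prs_risk - gail_risk))))
  } else {
    data.frame(statistic = character(0), value = numeric(0))
  }

  kappa_tab <- if (n >= 2) {
    pairs <- utils::combn(names(flags), 2L)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      kt <- cohens_kappa(flags[[pairs[1L, j]]], flags[[pairs[2L, j]]])
      data.frame(criterion_a = pairs[1L, j], criterion_b = pairs[2L, j],
                 kappa = kt$kappa, p_value = kt$p_value, status = kt$status)
    }))
  } else {
    data.frame(criterion_a = character(0), criterion_b = character(0),
               kappa = numeric(0), p_value = numeric(0), status = character(0))
  }

  age_table <- suppressWarnings(incremental_by_age(cls, cohort$age))
  summ <- cohort_summary(cohort, prs_risk, gail_risk)

  result <- list(cohort = cohort,
                 scores = data.frame(id = cohort$id, raw = raw, z = z),
                 classification = cls, summary = summ,
                 risk_comparison = risk_comparison, kappa = kappa_tab,
                 venn = venn, venn_young = venn_young, age_table = age_table,
                 calibration = calib, case_mean_z = case_mean_z,
                 output_dir = config$output_dir)

  if (write) stage("write_report", .write_report(result, config))
  invisible(result)
}

.write_report <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  tsv <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                            row.names = FALSE, quote = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(config$output_dir, recursive = TRUE))
  tsv(result$summary, "cohort_summary.tsv")
  tsv(result$classification, "classification.tsv")
  tsv(result$scores, "scores.tsv")
  tsv(result$risk_comparison, "risk_comparison.tsv")
  tsv(result$kappa, "kappa.tsv")
  tsv(result$venn$regions, "venn_regions.tsv")
  if (!is.null(result$venn_young))
    tsv(result$venn_young$regions, "venn_regions_young.tsv")
  tsv(result$age_table, "age_table.tsv")
  cfg <- config
  cfg$simulation <- if (!is.null(cfg$simulation))
    utils::modifyList(unclass(cfg$simulation),
                      list(allele_freqs = sprintf("<%d frequencies>",
                             length(cfg$simulation$allele_freqs)),
                           riskfactor_freqs = lapply(
                             cfg$simulation$riskfactor_freqs, as.list)))
  writeLines(yaml::as.yaml(unclass(cfg)), p("config_resolved.yaml"))
  log_lines <- c(
    sprintf("riskstrat pipeline run, seed %d", config$seed),
    sprintf("cohort size: %d", nrow(result$cohort)),
    sprintf("any_high: %d (%.1f%%)", sum(result$classification$any_high),
            if (nrow(result$cohort)) 100 * mean(result$classification$any_high)
            else NA_real_),
    if (!is.na(result$case_mean_z))
      sprintf("case mean standardized PRS: %.4f", result$case_mean_z))
  writeLines(log_lines, p("run_log.txt"))
  ok <- TRUE
  invisible(config$output_dir)
}
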