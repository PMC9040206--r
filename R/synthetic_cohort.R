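#' Default risk-factor category frequencies for simulated cohorts
#'
#' Marginal frequencies typical of an Asian breast-cancer case series:
#' menarche and age-at-first-birth category frequencies, ever-biopsy,
#' first-degree family history of breast (15%) and ovarian (2%) cancer, and
#' PTV carriership (5%).  Explicit `unknown` categories are generated so that
#' downstream handling of unknowns is exercised.
#'
#' @return Named list of probability vectors, each summing to 1.
#' @export
default_riskfactor_freqs <- function() {
  list(
    menarche = c("ge14" = 2212, "12to13" = 3968, "lt12" = 803,
                 "unknown" = 617) / 7600,
    first_birth = c("lt20" = 335, "20to25" = 1479, "25to30" = 2289,
                    "ge30" = 1792, "nulliparous" = 1294, "unknown" = 411) / 7600,
    biopsy = c("no" = 0.90, "yes" = 0.10),
    fh_breast = c("no" = 0.85, "yes" = 0.15),
    fh_ovarian = c("no" = 0.98, "yes" = 0.02),
    ptv = c("no" = 0.95, "yes" = 0.05),
    ethnicity = c("Chinese" = 5724, "Malay" = 1145, "Indian" = 645,
                  "Other" = 86) / 7600,
    case_type = c("incident" = 4511, "prevalent" = 3089) / 7600
  )
}

#' Simulation configuration
#'
#' Bundles everything [simulate_cohort()] needs.  Frequencies default to
#' [default_riskfactor_freqs()]; allele frequencies default to the bundled
#' synthetic 313-variant panel; ages to a truncated normal with median 52 and
#' interquartile range 45-59, truncated to \[30, 75\].
#'
#' @param n_individuals cohort size (>= 0).
#' @param allele_freqs effect-allele frequencies, strictly inside (0, 1).
#' @param prs_log_or_per_sd per-SD log odds ratio of the PRS used when cases
#'   are sampled by risk.
#' @param riskfactor_freqs named list of category probability maps; each must
#'   sum to 1 within 1e-9.
#' @param age_range ages are truncated to this closed interval.
#' @param age_mean,age_sd parameters of the (pre-truncation) normal age
#'   distribution.
#' @param missing_rate genotype missingness rate in \[0, 1).
#' @param seed integer seed; identical configs give byte-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       allele_freqs = NULL,
                       prs_log_or_per_sd = log(1.61),
                       riskfactor_freqs = default_riskfactor_freqs(),
                       age_range = c(30, 75),
                       age_mean = 52, age_sd = 10.4,
                       missing_rate = 0,
                       seed = 1L) {
  variant_ids <- NULL; counted_allele <- NULL; other_allele <- NULL
  if (is.null(allele_freqs)) {
    w <- load_weights(system.file("extdata", "prs313_synthetic.tsv",
                                  package = "riskstrat"))
    allele_freqs <- w$allele_freq
    variant_ids <- w$id
    counted_allele <- w$effect_allele
    other_allele <- w$other_allele
  }
  if (length(n_individuals) != 1L || is.na(n_individuals) || n_individuals < 0)
    stop("n_individuals must be a single non-negative count")
  if (any(allele_freqs <= 0 | allele_freqs >= 1) || any(!is.finite(allele_freqs)))
    stop("allele_freqs must lie strictly inside (0, 1)")
  for (nm in names(riskfactor_freqs)) {
    p <- riskfactor_freqs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("riskfactor_freqs$", nm, " must be non-negative and sum to 1")
  }
  if (!is.finite(prs_log_or_per_sd)) stop("prs_log_or_per_sd must be finite")
  structure(list(n_individuals = as.integer(n_individuals),
                 allele_freqs = allele_freqs,
                 prs_log_or_per_sd = prs_log_or_per_sd,
                 riskfactor_freqs = riskfactor_freqs,
                 age_range = age_range, age_mean = age_mean, age_sd = age_sd,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 variant_ids = variant_ids, counted_allele = counted_allele,
                 other_allele = other_allele),
            class = "sim_config")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each dosage is the sum of two independent Bernoulli draws at the variant's
#' effect-allele frequency, so genotype classes follow Hardy-Weinberg
#' proportions \eqn{(1-p)^2, 2p(1-p), p^2}.  Missing entries (NA) are
#' introduced completely at random at rate `missing_rate`.
#'
#' @param freqs effect-allele frequencies in (0, 1), one per variant.
#' @param n number of individuals.
#' @param missing_rate proportion of entries set missing, in \[0, 1).
#' @param seed integer seed.
#' @param ids variant identifiers (column names); default `snp_1..snp_m`.
#' @return An `n x m` integer matrix of dosages in \{0, 1, 2\} or NA, with
#'   variant ids as column names and attributes `counted_allele` /
#'   `other_allele` (simulated dosages count the effect allele, labelled
#'   "E"/"O" unless `ids` come with alleles attached).
#' @examples
#' g <- simulate_genotypes(c(0.3, 0.5), n = 4, seed = 7)
#' @export
simulate_genotypes <- function(freqs, n, missing_rate = 0, seed = 1L,
                               ids = NULL, counted_allele = NULL,
                               other_allele = NULL) {
  bad <- which(!is.finite(freqs) | freqs <= 0 | freqs >= 1)
  if (length(bad))
    stop("simulate_genotypes: allele frequency out of (0,1) at variant index ",
         paste(bad, collapse = ", "))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("simulate_genotypes: missing_rate must be in [0, 1)")
  m <- length(freqs)
  if (is.null(ids)) ids <- paste0("snp_", seq_len(m))
  if (is.null(counted_allele)) counted_allele <- rep("E", m)
  if (is.null(other_allele)) other_allele <- rep("O", m)
  set.seed(seed)
  g <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n,
              ncol = m, dimnames = list(NULL, ids))
  if (missing_rate > 0 && n * m > 0)
    g[stats::runif(n * m) < missing_rate] <- NA_integer_
  genotype_matrix(g, counted_allele = counted_allele,
                  other_allele = other_allele)
}

#' Construct a genotype dosage matrix
#'
#' A plain integer matrix of allele dosages with bookkeeping for which allele
#' each column counts, so scores can be computed regardless of reported
#' orientation.
#'
#' @param dosages `n x m` matrix with values in \{0, 1, 2\} or NA; column
#'   names are variant ids.
#' @param counted_allele,other_allele character vectors, one per variant: the
#'   allele whose copies `dosages` counts and the alternative allele.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, counted_allele, other_allele) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    stop("genotype_matrix: dosage columns must be named by variant id")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("genotype_matrix: dosages must be 0, 1, 2 or NA")
  if (length(counted_allele) != ncol(dosages) ||
      length(other_allele) != ncol(dosages))
    stop("genotype_matrix: one counted/other allele per variant required")
  storage.mode(dosages) <- "integer"
  structure(dosages, counted_allele = counted_allele,
            other_allele = other_allele, class = c("genotype_matrix", "matrix"))
}

.rcat <- function(n, p) {
  if (n == 0L) return(character(0))
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Simulate a cohort with configurable marginal structure
#'
#' Draws each questionnaire field independently from its configured category
#' map (the joint structure of real cohorts is not modelled; see the methods
#' vignette), ages from a truncated normal, and genotypes under
#' Hardy-Weinberg equilibrium.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cohort` (data.frame: `id`, `age`,
#'   `ethnicity`, `case_type`, `menarche`, `first_birth`, `biopsy`,
#'   `fh_breast`, `fh_ovarian`, `ptv_carrier`) and `genotypes` (a
#'   [genotype_matrix()] with one row per individual).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  set.seed(config$seed)
  rf <- config$riskfactor_freqs
  lo <- config$age_range[1L]; hi <- config$age_range[2L]
  # truncated-normal ages via inverse-CDF so n draws are always consumed
  plo <- stats::pnorm(lo, config$age_mean, config$age_sd)
  phi <- stats::pnorm(hi, config$age_mean, config$age_sd)
  age <- stats::qnorm(plo + stats::runif(n) * (phi - plo),
                      config$age_mean, config$age_sd)
  cohort <- data.frame(
    id = if (n > 0) sprintf("ind_%06d", seq_len(n)) else character(0),
    age = age,
    ethnicity = .rcat(n, rf$ethnicity),
    case_type = .rcat(n, rf$case_type),
    menarche = .rcat(n, rf$menarche),
    first_birth = .rcat(n, rf$first_birth),
    biopsy = .rcat(n, rf$biopsy),
    fh_breast = .rcat(n, rf$fh_breast) == "yes",
    fh_ovarian = .rcat(n, rf$fh_ovarian) == "yes",
    ptv_carrier = .rcat(n, rf$ptv) == "yes",
    stringsAsFactors = FALSE)
  genotypes <- simulate_genotypes(config$allele_freqs, n,
                                  missing_rate = config$missing_rate,
                                  seed = config$seed + 1L,
                                  ids = config$variant_ids,
                                  counted_allele = config$counted_allele,
                                  other_allele = config$other_allele)
  list(cohort = cohort, genotypes = genotypes)
}

#' Sample cases proportionally to exponential risk
#'
#' Draws `n_cases` individuals without replacement with inclusion probability
#' proportional to \eqn{\exp(\beta z)}, the rare-disease log-linear risk
#' model: sampling cases this way from a standard-normal PRS population makes
#' the case PRS distribution N(\eqn{\beta}, 1).  Uses exponential-key
#' weighted reservoir sampling, which is exact and O(n log n).
#'
#' @param standardized_prs numeric vector of standardized scores, one per
#'   individual in the source population.
#' @param beta per-SD log odds ratio.
#' @param n_cases number of cases to draw.
#' @param seed integer seed.
#' @return Integer vector of the sampled indices (sorted).
#' @examples
#' z <- rnorm(1000)
#' idx <- sample_cases_by_risk(z, beta = 0.6, n_cases = 100, seed = 1)
#' @export
sample_cases_by_risk <- function(standardized_prs, beta, n_cases, seed = 1L) {
  n <- length(standardized_prs)
  if (!is.finite(beta)) stop("beta must be finite")
  if (n_cases > n) stop("n_cases (", n_cases, ") exceeds population size (", n, ")")
  if (n_cases == 0L) return(integer(0))
  set.seed(seed)
  # Efraimidis-Spirakis: smallest Exp(1)/w keys form an exact weighted
  # without-replacement sample; log-scale weights avoid overflow
  logw <- beta * (standardized_prs - max(standardized_prs))
  keys <- stats::rexp(n) / exp(logw)
  sort(order(keys)[seq_len(n_cases)])
}
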