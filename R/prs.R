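#' Load a PRS weights table
#'
#' Tab-separated with header columns `id`, `effect_allele`, `other_allele`,
#' `weight` (log odds per effect allele); extra columns (e.g. a reference
#' `allele_freq`) are kept.
#'
#' @param path path to the weights TSV.
#' @return A data.frame of class `prs_weights`.
#' @export
load_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "effect_allele", "other_allele", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("load_weights: missing column(s): ", paste(miss, collapse = ", "))
  prs_weights(w)
}

#' Validate a PRS weights table
#'
#' @param w data.frame with columns `id`, `effect_allele`, `other_allele`,
#'   `weight`.
#' @return `w` with class `prs_weights`.
#' @export
prs_weights <- function(w) {
  dup <- w$id[duplicated(w$id)]
  if (length(dup))
    stop("prs_weights: duplicated variant id(s): ",
         paste(unique(dup), collapse = ", "))
  if (any(w$effect_allele == w$other_allele))
    stop("prs_weights: effect_allele must differ from other_allele")
  if (any(!is.finite(w$weight)))
    stop("prs_weights: weights must be finite")
  class(w) <- c("prs_weights", "data.frame")
  w
}

#' Write a PRS weights table
#' @param w a `prs_weights` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  utils::write.table(w, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.is_ambiguous <- function(a, b) .COMPLEMENT[a] == b

#' Compute raw polygenic scores
#'
#' The raw score is the weighted sum of effect-allele dosages,
#' \eqn{s_i = \sum_j w_j d_{ij}} (sum semantics, no averaging — a
#' scoresum-style total).  Dosage columns reporting the other allele are
#' complemented (`d = 2 - d'`) so scores do not depend on reported
#' orientation.  Variants whose alleles match the weights in neither
#' orientation are excluded with a warning; strand-ambiguous (A/T, C/G)
#' variants are matched as reported and counted in a message.
#'
#' @param genotypes a [genotype_matrix()] (variant ids as column names).
#' @param weights a `prs_weights` table ([load_weights()]).
#' @param missing_policy `"mean_impute"` (default): a missing dosage
#'   contributes \eqn{w_j \cdot 2\hat f_j} with \eqn{\hat f_j} the
#'   effect-allele frequency estimated from non-missing individuals;
#'   `"omit"`: missing dosages contribute 0.
#' @return Numeric vector of raw scores, one per individual, with attribute
#'   `n_excluded` (variants dropped for allele mismatch or absence).
#' @examples
#' g <- genotype_matrix(matrix(2L, 1, 1, dimnames = list(NULL, "rs1")), "A", "G")
#' w <- prs_weights(data.frame(id = "rs1", effect_allele = "A",
#'                             other_allele = "G", weight = 0.1))
#' compute_raw_prs(g, w)  # 0.2
#' @export
compute_raw_prs <- function(genotypes, weights,
                            missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  counted <- attr(genotypes, "counted_allele")
  other <- attr(genotypes, "other_allele")
  ids <- colnames(genotypes)
  score <- numeric(nrow(genotypes))
  n_used <- 0L; n_flipped <- 0L; n_ambig <- 0L
  skipped <- character(0)
  for (j in seq_len(nrow(weights))) {
    k <- match(weights$id[j], ids)
    if (is.na(k)) { skipped <- c(skipped, weights$id[j]); next }
    ea <- weights$effect_allele[j]; oa <- weights$other_allele[j]
    if (counted[k] == ea && other[k] == oa) {
      d <- genotypes[, k]
    } else if (counted[k] == oa && other[k] == ea) {
      d <- 2L - genotypes[, k]
      n_flipped <- n_flipped + 1L
    } else {
      skipped <- c(skipped, weights$id[j]); next
    }
    if (ea %in% names(.COMPLEMENT) && oa %in% names(.COMPLEMENT) &&
        .is_ambiguous(ea, oa))
      n_ambig <- n_ambig + 1L
    if (anyNA(d)) {
      if (missing_policy == "mean_impute") {
        f <- mean(d, na.rm = TRUE) / 2
        if (is.nan(f)) f <- 0  # variant missing in everyone
        d[is.na(d)] <- 2 * f
      } else {
        d[is.na(d)] <- 0
      }
    }
    score <- score + weights$weight[j] * d
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    stop("compute_raw_prs: no weight variant could be matched to the genotypes")
  if (length(skipped))
    warning(length(skipped), " variant(s) excluded (absent or allele mismatch): ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")
  if (n_ambig > 0L)
    message(n_ambig, " strand-ambiguous (A/T or C/G) variant(s) matched as reported")
  attr(score, "n_excluded") <- length(skipped)
  score
}

#' Reference mean and SD of a standard population
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of raw
#' scores in a control population, used to standardize scores.
#'
#' @param raw_scores_of_controls numeric vector, at least 2 finite values.
#' @param population label carried along (e.g. control ethnicity).
#' @return List of class `reference_stats` with `mean`, `sd`, `population`.
#' @export
compute_reference_stats <- function(raw_scores_of_controls,
                                    population = "controls") {
  x <- raw_scores_of_controls
  if (length(x) < 2L || any(!is.finite(x)))
    stop("compute_reference_stats: need at least 2 finite scores")
  s <- stats::sd(x)
  if (s == 0)
    stop("compute_reference_stats: zero variance; standardization undefined")
  structure(list(mean = mean(x), sd = s, population = population),
            class = "reference_stats")
}

#' Standardize raw scores against a reference population
#'
#' @param raw numeric vector of raw scores.
#' @param ref a `reference_stats` object ([compute_reference_stats()]).
#' @return `(raw - ref$mean) / ref$sd`.
#' @export
standardize_prs <- function(raw, ref) {
  stopifnot(inherits(ref, "reference_stats"), ref$sd > 0)
  (raw - ref$mean) / ref$sd
}
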