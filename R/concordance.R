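#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' observed agreement \eqn{p_o} and chance agreement \eqn{p_e} from the
#' marginals.  The p-value tests \eqn{\kappa = 0} with the large-sample
#' normal approximation (Fleiss' null standard error).
#'
#' @param a,b logical vectors of equal length >= 2.
#' @return List of class `kappa_test`: `kappa`, `p_o`, `p_e`, `se0`,
#'   `statistic` (z), `p_value`, `n`, `status` (`"ok"` or `"degenerate"`
#'   when \eqn{p_e = 1} leaves kappa undefined, in which case the numeric
#'   fields are NA).
#' @examples
#' a <- c(rep(TRUE, 25), rep(FALSE, 75))
#' b <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 65))
#' cohens_kappa(a, b)$kappa  # 0.625
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("cohens_kappa: unequal lengths")
  n <- length(a)
  if (n < 2L) stop("cohens_kappa: need at least 2 observations")
  a <- as.logical(a); b <- as.logical(b)
  p11 <- mean(a & b); p10 <- mean(a & !b)
  p01 <- mean(!a & b); p00 <- mean(!a & !b)
  pa <- c(p11 + p10, p01 + p00)          # marginals of a (TRUE, FALSE)
  pb <- c(p11 + p01, p10 + p00)
  p_o <- p11 + p00
  p_e <- sum(pa * pb)
  if (1 - p_e < .Machine$double.eps * 8)
    return(structure(list(kappa = NA_real_, p_o = p_o, p_e = p_e,
                          se0 = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, n = n, status = "degenerate"),
                     class = "kappa_test"))
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss-Cohen-Everitt null SE
  se0 <- sqrt((p_e + p_e^2 - sum(pa * pb * (pa + pb))) / (n * (1 - p_e)^2))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, se0 = se0,
                 statistic = z, p_value = p, n = n, status = "ok"),
            class = "kappa_test")
}

#' @export
print.kappa_test <- function(x, ...) {
  if (x$status == "degenerate") {
    cat("Cohen's kappa: undefined (chance agreement = 1)\n")
  } else {
    cat(sprintf("Cohen's kappa = %.4f (p_o = %.4f, p_e = %.4f), z = %.3f, p = %.3g, n = %d\n",
                x$kappa, x$p_o, x$p_e, x$statistic, x$p_value, x$n))
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Spearman's rho on average-tie ranks.  Constant input makes the
#' correlation undefined; this is reported as a degenerate status rather
#' than NA arithmetic.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho` and `status` (`"ok"`/`"degenerate"`).
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("rank_correlation: unequal lengths")
  if (length(x) < 3L) stop("rank_correlation: need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, status = "degenerate"))
  list(rho = stats::cor(x, y, method = "spearman"), status = "ok")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped before ranking (the classical convention);
#' the null distribution is exact for up to 25 nonzero untied differences
#' and a tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_max largest number of nonzero differences for which the
#'   exact distribution is used (default 25).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`
#'   (two-sided), `n_nonzero`, `method`, `status` (`"ok"`/`"degenerate"`
#'   when all differences are zero).
#' @export
paired_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop("paired_signed_rank: unequal lengths")
  d <- x - y
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
                method = "none", status = "degenerate"))
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = length(d),
       method = if (exact) "exact" else "normal approximation",
       status = "ok")
}

#' Disjoint-region overlap counts for binary criteria
#'
#' Counts every membership pattern of up to six binary criteria (the Venn
#' decomposition), plus per-criterion marginals and the union.
#'
#' @param flags named list of logical vectors of equal length (k <= 6).
#' @return List of class `overlap_summary`: `regions` (data.frame `pattern`
#'   -- a string of 0/1 in `names(flags)` order -- and `count`, all
#'   \eqn{2^k} rows), `marginals` (named counts), `proportions`, `union`,
#'   `n`.
#' @examples
#' venn_counts(list(A = c(TRUE, TRUE, FALSE), B = c(FALSE, TRUE, TRUE)))
#' @export
venn_counts <- function(flags) {
  k <- length(flags)
  if (k < 1L || k > 6L) stop("venn_counts: between 1 and 6 criteria required")
  if (is.null(names(flags)) || any(!nzchar(names(flags))))
    names(flags) <- paste0("criterion_", seq_len(k))
  n <- length(flags[[1L]])
  if (any(lengths(flags) != n)) stop("venn_counts: unequal lengths")
  mat <- vapply(flags, as.logical, logical(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, names(flags)))
  all_patterns <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE],
                        1L, paste, collapse = "")
  pattern <- if (n > 0) apply(mat, 1L, function(r) paste(as.integer(r), collapse = ""))
             else character(0)
  counts <- table(factor(pattern, levels = all_patterns))
  regions <- data.frame(pattern = all_patterns, count = as.integer(counts),
                        stringsAsFactors = FALSE)
  marginals <- if (n > 0) colSums(mat) else stats::setNames(numeric(k), names(flags))
  structure(list(regions = regions,
                 marginals = stats::setNames(as.integer(marginals), names(flags)),
                 proportions = if (n > 0) marginals / n else marginals,
                 union = if (n > 0) sum(rowSums(mat) > 0) else 0L,
                 n = n),
            class = "overlap_summary")
}

#' Incremental high-risk identification by 5-year age group
#'
#' For each 5-year age bin and each prefix of an ordered criterion sequence,
#' the proportion of individuals flagged by the union of the prefix's
#' criteria — the "what does adding each criterion buy" view.  Default
#' sequence: family history, then Gail, then PRS, then PTV.
#'
#' @param classification a [classify_high_risk()] result (or any data.frame
#'   with the criterion columns).
#' @param ages numeric vector aligned with `classification`.
#' @param sequence ordered subset of `c("fh_high", "gail_high", "prs_high",
#'   "ptv_carrier")`.
#' @param bins lower bin edges; bins are `[b, b+5)` with the last bin closed
#'   at its upper edge.  Ages outside are pooled into an `"other"` bin with
#'   a warning.
#' @return Data.frame: `age_group`, `n`, then one cumulative-proportion
#'   column per prefix (`upto_<criterion>`), non-decreasing left to right.
#' @export
incremental_by_age <- function(classification, ages,
                               sequence = c("fh_high", "gail_high",
                                            "prs_high", "ptv_carrier"),
                               bins = seq(30, 70, by = 5)) {
  if (length(ages) != nrow(classification))
    stop("incremental_by_age: ages must align with classification rows")
  bad <- setdiff(sequence, names(classification))
  if (length(bad))
    stop("incremental_by_age: unknown criterion: ", paste(bad, collapse = ", "))
  top <- max(bins) + 5
  lab <- sprintf("%d-%d", bins, bins + 5L - 1L)
  grp <- ifelse(ages >= min(bins) & ages <= top,
                lab[pmin(findInterval(ages, bins), length(bins))], "other")
  if (any(grp == "other") )
    warning(sum(grp == "other"), " individual(s) outside the configured age bins")
  levs <- c(lab, if (any(grp == "other")) "other")
  grp <- factor(grp, levels = levs)
  running <- rep(FALSE, nrow(classification))
  out <- data.frame(age_group = levs, n = as.integer(table(grp)),
                    stringsAsFactors = FALSE)
  for (crit in sequence) {
    running <- running | classification[[crit]]
    out[[paste0("upto_", crit)]] <-
      as.numeric(tapply(running, grp, mean, default = NaN))
  }
  out
}
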