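#' The nine-gene breast-cancer predisposition panel
#'
#' Genes in which protein-truncating variants are counted as high-risk
#' carriership.
#'
#' @return Character vector of gene symbols.
#' @export
ptv_panel_genes <- function() {
  c("ATM", "BRCA1", "BRCA2", "CHEK2", "PALB2", "BARD1", "RAD51C", "RAD51D",
    "TP53")
}

.PTV_CLASSES <- c("nonsense_snv", "frameshift_indel", "splice_disrupting_snv")
.CONSEQUENCES <- c(.PTV_CLASSES, "other")

#' Classify protein-truncating-variant carriership
#'
#' An individual is a carrier if they have at least one variant whose
#' consequence is a nonsense SNV, frameshift indel, or splice-disrupting
#' SNV, in a panel gene, and not in the gene's last exon.  Last-exon
#' truncating variants are excluded because they are expected to escape
#' nonsense-mediated decay.
#'
#' @param variants data.frame with columns `individual_id`, `gene`,
#'   `consequence` (one of `nonsense_snv`, `frameshift_indel`,
#'   `splice_disrupting_snv`, `other`), `in_last_exon` (logical).
#' @param individual_ids ids to classify; defaults to the ids present in
#'   `variants`.  Ids without qualifying variants are non-carriers.
#' @param panel gene set; defaults to [ptv_panel_genes()].
#' @return Named logical vector, one element per `individual_ids`.
#' @examples
#' v <- data.frame(individual_id = "a", gene = "BRCA1",
#'                 consequence = "nonsense_snv", in_last_exon = FALSE)
#' classify_ptv(v)
#' @export
classify_ptv <- function(variants, individual_ids = NULL,
                         panel = ptv_panel_genes()) {
  need <- c("individual_id", "gene", "consequence", "in_last_exon")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("classify_ptv: missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!variants$consequence %in% .CONSEQUENCES)
  if (length(bad))
    stop("classify_ptv: unknown consequence '",
         variants$consequence[bad[1L]], "' at record ", bad[1L])
  if (is.null(individual_ids)) individual_ids <- unique(variants$individual_id)
  hit <- variants$consequence %in% .PTV_CLASSES &
    variants$gene %in% panel & !variants$in_last_exon
  carriers <- unique(variants$individual_id[hit])
  stats::setNames(individual_ids %in% carriers, individual_ids)
}

#' Apply the four high-risk criteria
#'
#' Flags each individual as high risk by (1) first-degree family history of
#' breast or ovarian cancer, (2) PRS 5-year absolute risk at the threshold
#' or above, (3) Gail-model 5-year absolute risk at the threshold or above,
#' (4) PTV carriership; `any_high` is their union.  The threshold comparison
#' is inclusive (`>=`) by default; `strict = TRUE` uses `>`.
#'
#' @param cohort data.frame with logical columns `fh_breast`, `fh_ovarian`,
#'   `ptv_carrier` (and optionally `id`).
#' @param prs_risk,gail_risk numeric vectors of 5-year absolute risks in
#'   \[0, 1\], aligned with `cohort` rows.
#' @param threshold high-risk absolute-risk threshold (default 0.013, the
#'   5-year risk of an average 50-year-old under US white-female rates).
#' @param strict if TRUE use a strict `>` comparison.
#' @return Data.frame of class `risk_classification`: `id`, `fh_high`,
#'   `prs_risk_5y`, `gail_risk_5y`, `prs_high`, `gail_high`, `ptv_carrier`,
#'   `any_high`.
#' @export
classify_high_risk <- function(cohort, prs_risk, gail_risk, threshold = 0.013,
                               strict = FALSE) {
  n <- nrow(cohort)
  if (length(prs_risk) != n || length(gail_risk) != n)
    stop("classify_high_risk: risk vectors must align with the cohort (",
         n, " rows)")
  if (threshold <= 0 || threshold >= 1)
    stop("classify_high_risk: threshold must be in (0, 1)")
  if (n && (any(prs_risk < 0 | prs_risk > 1) || any(gail_risk < 0 | gail_risk > 1)))
    stop("classify_high_risk: risks must lie in [0, 1]")
  cmp <- if (strict) `>` else `>=`
  out <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else as.character(seq_len(n)),
    fh_high = cohort$fh_breast | cohort$fh_ovarian,
    prs_risk_5y = prs_risk,
    gail_risk_5y = gail_risk,
    prs_high = cmp(prs_risk, threshold),
    gail_high = cmp(gail_risk, threshold),
    ptv_carrier = cohort$ptv_carrier,
    stringsAsFactors = FALSE)
  out$any_high <- out$fh_high | out$prs_high | out$gail_high | out$ptv_carrier
  class(out) <- c("risk_classification", "data.frame")
  out
}

#' Simulate annotated variant records consistent with carrier flags
#'
#' For each flagged carrier, emits one qualifying PTV (random panel gene and
#' truncating class, not in the last exon); sprinkles non-qualifying records
#' (missense, last-exon PTVs, off-panel genes) over the cohort so that the
#' PTV classifier's exclusion rules are exercised.  [classify_ptv()] applied
#' to the output reproduces the input flags exactly.
#'
#' @param ids individual ids.
#' @param carrier logical vector aligned with `ids`.
#' @param decoy_rate proportion of individuals receiving a non-qualifying
#'   record.
#' @param seed integer seed.
#' @return Data.frame of variant records (see [classify_ptv()]).
#' @export
simulate_ptv_variants <- function(ids, carrier, decoy_rate = 0.05, seed = 1L) {
  stopifnot(length(ids) == length(carrier))
  set.seed(seed)
  panel <- ptv_panel_genes()
  rec <- list()
  nc <- sum(carrier)
  if (nc > 0)
    rec$carrier <- data.frame(
      individual_id = ids[carrier],
      gene = sample(panel, nc, replace = TRUE),
      consequence = sample(.PTV_CLASSES, nc, replace = TRUE),
      in_last_exon = FALSE, stringsAsFactors = FALSE)
  decoy <- stats::runif(length(ids)) < decoy_rate
  nd <- sum(decoy)
  if (nd > 0) {
    kind <- sample(3L, nd, replace = TRUE)
    rec$decoy <- data.frame(
      individual_id = ids[decoy],
      gene = ifelse(kind == 3L, "GREB1", sample(panel, nd, replace = TRUE)),
      consequence = ifelse(kind == 1L, "other",
                           sample(.PTV_CLASSES, nd, replace = TRUE)),
      in_last_exon = kind == 2L, stringsAsFactors = FALSE)
  }
  if (!length(rec))
    return(data.frame(individual_id = character(0), gene = character(0),
                      consequence = character(0), in_last_exon = logical(0)))
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}
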