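#' Write a cohort table
#'
#' Tab-separated with header; logical columns written as TRUE/FALSE.
#'
#' @param cohort data.frame as produced by [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path input path.
#' @return data.frame.
#' @export
load_cohort <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write genotype dosages as a variant x individual matrix
#'
#' Tab-separated: columns `id`, `counted_allele`, `other_allele`, then one
#' column per individual; missing dosages written as NA.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @param individual_ids column labels; default `ind_1..ind_n`.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(genotypes, path, individual_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes)
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(n))
  out <- data.frame(id = colnames(genotypes),
                    counted_allele = attr(genotypes, "counted_allele"),
                    other_allele = attr(genotypes, "other_allele"),
                    stringsAsFactors = FALSE)
  dm <- t(unclass(genotypes))
  colnames(dm) <- individual_ids
  utils::write.table(cbind(out, dm), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dosage matrix written by [write_dosage_matrix()]
#' @param path input path.
#' @return A [genotype_matrix()].
#' @export
load_dosage_matrix <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "counted_allele", "other_allele")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("load_dosage_matrix: missing column(s): ", paste(miss, collapse = ", "))
  dm <- t(as.matrix(raw[, setdiff(names(raw), need), drop = FALSE]))
  colnames(dm) <- raw$id
  genotype_matrix(dm, raw$counted_allele, raw$other_allele)
}

#' Write genotype dosages as a minimal VCF
#'
#' One record per variant with the counted allele as ALT (so the DS field is
#' the ALT dosage), REF the other allele; per-sample FORMAT field `DS`.
#' Coordinates are synthetic placeholders unless ids are `chrom:pos`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path (plain `.vcf`).
#' @param individual_ids sample names.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, individual_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes)
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(n))
  ids <- colnames(genotypes)
  cp <- strsplit(ids, ":", fixed = TRUE)
  chrom <- vapply(cp, function(x) if (length(x) >= 2) x[1L] else "1", "")
  pos <- vapply(cp, function(x) if (length(x) >= 2) x[2L] else NA_character_, "")
  pos[is.na(pos)] <- as.character(seq_len(ncol(genotypes)) * 1000L)[is.na(pos)]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (counted) allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individual_ids), collapse = "\t"))
  ds <- apply(unclass(genotypes), 2L, function(col) {
    v <- ifelse(is.na(col), ".", as.character(col))
    v
  })
  if (n == 1L) ds <- matrix(ds, nrow = 1L)
  body <- vapply(seq_along(ids), function(j) {
    paste(c(chrom[j], pos[j], ids[j], attr(genotypes, "other_allele")[j],
            attr(genotypes, "counted_allele")[j], ".", "PASS", ".", "DS",
            ds[, j]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS FORMAT field
#'
#' Uses vcfR; the counted allele is the ALT allele.
#'
#' @param path path to a VCF.
#' @return A [genotype_matrix()].
#' @export
load_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("load_genotypes_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  dm <- t(ds)
  colnames(dm) <- unname(fix[, "ID"])
  genotype_matrix(dm, counted_allele = unname(fix[, "ALT"]),
                  other_allele = unname(fix[, "REF"]))
}

#' Write PRS scores
#'
#' TSV with columns `id`, `raw`, `z`, `population`.
#'
#' @param ids individual ids.
#' @param raw,z raw and standardized scores.
#' @param population reference-population label.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(ids, raw, z, population, path) {
  utils::write.table(data.frame(id = ids, raw = raw, z = z,
                                population = population),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
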