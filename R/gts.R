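## Gene-level mutation-severity scoring: MAF categories, the GTS score,
## deleterious counts, percentiles and deciles.

#' Categorise minor allele frequencies
#'
#' The four categories partition `(0, 1]`: rare (`MAF < 0.0001`), low
#' (`0.0001 <= MAF < 0.001`), medium (`0.001 <= MAF < 0.01`) and common
#' (`MAF >= 0.01`).
#'
#' @param maf Numeric vector of minor allele frequencies in `(0, 1]`.
#' @return Character vector of category labels.
#' @export
maf_category <- function(maf) {
  if (any(is.na(maf) | maf <= 0 | maf > 1)) {
    stop("MAF values must lie in (0, 1]", call. = FALSE)
  }
  ifelse(maf < 1e-4, "rare",
         ifelse(maf < 1e-3, "low",
                ifelse(maf < 1e-2, "medium", "common")))
}

#' Summarise the MAF spectrum of a variant catalog
#'
#' @param x A variant data frame with a `maf` column, or a numeric MAF
#'   vector, or a named vector of per-category counts.
#' @return Data frame with columns `category`, `count`, `percent` (counts sum
#'   to the catalog size; percentages to 100).
#' @export
summarize_maf_spectrum <- function(x) {
  levels <- c("rare", "low", "medium", "common")
  if (is.data.frame(x)) x <- x$maf
  if (!is.null(names(x)) && all(names(x) %in% levels)) {
    counts <- stats::setNames(numeric(4), levels)
    counts[names(x)] <- x
  } else {
    if (length(x) == 0) stop("empty catalog", call. = FALSE)
    counts <- table(factor(maf_category(x), levels = levels))
  }
  data.frame(category = levels, count = as.numeric(counts),
             percent = 100 * as.numeric(counts) / sum(counts))
}

## One record per (gene, position, mut), keeping the maximum MAF.
dedupe_savs <- function(variants) {
  key <- paste(variants$gene, variants$position, variants$mut)
  if (anyDuplicated(key)) {
    o <- order(-variants$maf)
    variants <- variants[o, , drop = FALSE]
    keep <- !duplicated(paste(variants$gene, variants$position,
                              variants$mut))
    dropped <- sum(!keep)
    variants <- variants[keep, , drop = FALSE]
    message("dropped ", dropped,
            " duplicate SAV record(s), keeping the maximum MAF")
  }
  variants
}

#' GTS: Gene Tolerance of rare SAVs
#'
#' The length-normalised, MAF-weighted sum of DeepSAV scores over a gene's
#' rare variants:
#' `GTS = sum_k DeepSAV_score(k) * MAF(k) / protein_len`, where the sum runs
#' over SAVs with `MAF < rare_maf_cutoff`.  Low GTS marks mutation-intolerant
#' genes (rare variation is absent or predicted benign); high GTS marks
#' tolerant genes.
#'
#' @param scores DeepSAV scores of the gene's SAVs (in `[0, 1]`).
#' @param maf Minor allele frequencies of the same SAVs (`> 0`).
#' @param protein_len Protein length in amino acids (>= 1).
#' @param rare_maf_cutoff Rare-SAV threshold (default 0.0001; SAVs at or
#'   above it are ignored).
#' @return Non-negative GTS score.
#' @export
gts_score <- function(scores, maf, protein_len, rare_maf_cutoff = 1e-4) {
  if (protein_len < 1) stop("protein_len must be >= 1", call. = FALSE)
  stopifnot(length(scores) == length(maf))
  rare <- maf < rare_maf_cutoff
  sum(scores[rare] * maf[rare]) / protein_len
}

#' Count predicted deleterious SAVs of a gene
#'
#' SAVs scoring strictly above `score_threshold`, by default restricted to
#' rare SAVs.
#'
#' @inheritParams gts_score
#' @param score_threshold DeepSAV score cutoff (strict `>`; default 0.75).
#' @param rare_only Restrict to `MAF < rare_maf_cutoff` (default TRUE).
#' @return Integer count.
#' @export
count_deleterious <- function(scores, maf, score_threshold = 0.75,
                              rare_only = TRUE, rare_maf_cutoff = 1e-4) {
  keep <- scores > score_threshold
  if (rare_only) keep <- keep & maf < rare_maf_cutoff
  sum(keep)
}

#' Inclusive percentile ranks (Excel PERCENTRANK.INC convention)
#'
#' The rank of each value is the number of values strictly below it divided
#' by `n - 1`; ties share the percentile of their first occurrence, the
#' minimum maps to 0 and the maximum to 1.
#'
#' @param x Numeric vector (length >= 2).
#' @return Percentiles in `[0, 1]`.
#' @export
percent_rank <- function(x) {
  if (length(x) < 2L) {
    stop("percentile transform needs at least 2 values", call. = FALSE)
  }
  (rank(x, ties.method = "min") - 1) / (length(x) - 1)
}

#' Decile of a percentile
#'
#' `floor(percentile * 10)` capped at 9, so the top-ranked gene falls in
#' decile 9.
#'
#' @param percentile Values in `[0, 1]`.
#' @return Integer deciles in `0..9`.
#' @export
percentile_decile <- function(percentile) {
  pmin(9L, as.integer(floor(percentile * 10)))
}

#' Gene tolerance table from scored variants
#'
#' Aggregates a scored variant catalog into one record per gene: GTS score,
#' inclusive percentile, decile, number of rare SAVs and number of predicted
#' deleterious rare SAVs (score > 0.75).  Genes without variants in the
#' catalog receive GTS 0.  Duplicate SAV records (same gene, position,
#' mutant) are collapsed to the maximum MAF.
#'
#' @param variants Data frame with columns `gene`, `position`, `mut`, `maf`,
#'   `deepsav_score`.
#' @param gene_lengths Data frame with columns `gene`, `protein_len`.
#' @param rare_maf_cutoff Rare-SAV threshold (default 0.0001).
#' @param score_threshold Deleterious-call threshold (default 0.75).
#' @return Data frame sorted ascending by GTS with columns `gene`, `gts`,
#'   `percentile`, `decile`, `n_rare_savs`, `n_deleterious`.
#' @export
gene_tolerance_table <- function(variants, gene_lengths,
                                 rare_maf_cutoff = 1e-4,
                                 score_threshold = 0.75) {
  stopifnot(all(c("gene", "maf", "deepsav_score") %in% names(variants)),
            all(c("gene", "protein_len") %in% names(gene_lengths)))
  if (nrow(gene_lengths) < 2L) {
    stop("percentile transform needs at least 2 genes", call. = FALSE)
  }
  variants <- dedupe_savs(variants)
  unknown <- setdiff(unique(variants$gene), gene_lengths$gene)
  if (length(unknown) > 0L) {
    stop("variants reference gene(s) without a length: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  by_gene <- split(variants, factor(variants$gene,
                                    levels = gene_lengths$gene))
  gts <- mapply(function(v, len) {
    gts_score(v$deepsav_score, v$maf, len, rare_maf_cutoff)
  }, by_gene, gene_lengths$protein_len)
  n_rare <- vapply(by_gene, function(v) sum(v$maf < rare_maf_cutoff),
                   numeric(1))
  n_del <- vapply(by_gene, function(v) {
    count_deleterious(v$deepsav_score, v$maf, score_threshold,
                      rare_only = TRUE, rare_maf_cutoff = rare_maf_cutoff)
  }, numeric(1))
  pct <- percent_rank(gts)
  out <- data.frame(gene = gene_lengths$gene, gts = as.numeric(gts),
                    percentile = pct, decile = percentile_decile(pct),
                    n_rare_savs = as.integer(n_rare),
                    n_deleterious = as.integer(n_del))
  out <- out[order(out$gts, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Write / read a gene tolerance table
#' @param x Gene tolerance table from [gene_tolerance_table()].
#' @param path File path.
#' @export
write_gene_tolerance_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_gene_tolerance_tsv
#' @export
read_gene_tolerance_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(gene = "character"))
}
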