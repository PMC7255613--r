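## Log2 odds enrichment of positional properties in variant subsets, and
## observed/expected disease-class ratios over gene sets.

#' Log2 odds enrichment of a property in a position subset
#'
#' `log2(p_subset / p_background)`, where each probability is the fraction of
#' positions carrying the property.  Positive values mean enrichment in the
#' subset relative to the background, negative depletion; a zero subset count
#' yields `-Inf` unless a pseudocount is supplied.
#'
#' @param count_in_subset,subset_size Property count and size of the subset.
#' @param count_in_background,background_size Property count and size of the
#'   background (typically all positions of the proteome).
#' @param pseudocount Added to both counts (and twice to both sizes) before
#'   forming probabilities; default 0.
#' @return Log2 odds score.
#' @export
property_log_odds <- function(count_in_subset, subset_size,
                              count_in_background, background_size,
                              pseudocount = 0) {
  stopifnot(subset_size > 0, background_size > 0,
            count_in_subset <= subset_size,
            count_in_background <= background_size)
  p_bg <- (count_in_background + pseudocount) /
    (background_size + 2 * pseudocount)
  if (p_bg == 0) stop("background probability is zero", call. = FALSE)
  p_sub <- (count_in_subset + pseudocount) / (subset_size + 2 * pseudocount)
  if (p_sub == 0) return(-Inf)
  log2(p_sub / p_bg)
}

#' Enrichment matrix of properties across variant subsets
#'
#' Computes one log2 odds cell per (property, subset), counting unique
#' positions.  Subsets are given as data frames of (gene, position) pairs —
#' typically the positions of pathogenic variants, or of catalog variants in
#' each MAF category; the background is the full position table.
#'
#' @param position_table Data frame with `gene`, `position` and one 0/1
#'   column per property (see [position_property_table()]).
#' @param subsets Named list of data frames, each with `gene` and `position`
#'   columns.
#' @param properties Property column names (default: all 0/1 columns of
#'   `position_table`).
#' @param pseudocount Passed to [property_log_odds()].
#' @return Data frame of class `enrichment_matrix`: one row per (property,
#'   subset) with the underlying counts and the log2 odds.
#' @export
enrichment_matrix <- function(position_table, subsets, properties = NULL,
                              pseudocount = 0) {
  stopifnot(all(c("gene", "position") %in% names(position_table)))
  if (is.null(properties)) {
    properties <- setdiff(names(position_table), c("gene", "position"))
  }
  bg_key <- paste(position_table$gene, position_table$position)
  stopifnot(!anyDuplicated(bg_key))
  n_bg <- nrow(position_table)
  bg_counts <- vapply(properties,
                      function(p) sum(position_table[[p]] >= 0.5),
                      numeric(1))
  absent <- bg_counts == 0
  if (any(absent)) {
    warning("property(ies) absent from the background, skipped: ",
            paste(properties[absent], collapse = ", "), call. = FALSE)
    properties <- properties[!absent]
    bg_counts <- bg_counts[!absent]
  }
  rows <- list()
  for (s in names(subsets)) {
    sub <- subsets[[s]]
    keys <- unique(paste(sub$gene, sub$position))
    idx <- match(keys, bg_key)
    if (anyNA(idx)) {
      stop("subset '", s, "' contains positions absent from the table",
           call. = FALSE)
    }
    if (length(idx) == 0L) {
      warning("subset '", s, "' is empty; skipped", call. = FALSE)
      next
    }
    for (p in properties) {
      cnt <- sum(position_table[[p]][idx] >= 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = s, property = p,
        count_in_subset = cnt, subset_size = length(idx),
        count_in_background = bg_counts[[p]], background_size = n_bg,
        log_odds = property_log_odds(cnt, length(idx), bg_counts[[p]], n_bg,
                                     pseudocount))
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(subset = character(0), property = character(0),
                      count_in_subset = numeric(0), subset_size = numeric(0),
                      count_in_background = numeric(0),
                      background_size = numeric(0), log_odds = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("enrichment_matrix", class(out))
  out
}

#' Plot an enrichment matrix
#'
#' Barplot of log2 odds per property, one panel group per subset; infinite
#' cells (zero subset counts) are dropped.
#'
#' @param x An [enrichment_matrix()] result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.enrichment_matrix <- function(x, ...) {
  x <- x[is.finite(x$log_odds), ]
  m <- tapply(x$log_odds, list(x$subset, x$property), identity)
  graphics::barplot(m, beside = TRUE, las = 2,
                    ylab = "log2 odds (subset vs background)",
                    legend.text = rownames(m), ...)
  invisible(x)
}

#' Observed/expected disease-class ratios for a gene set
#'
#' For each disease class, the ratio of its frequency among the gene set's
#' associations to its frequency among all associations in the table.
#' Classes whose expected association count falls below `min_expected` are
#' excluded (sparse classes).
#'
#' @param gene_set Character vector of gene identifiers.
#' @param gda Gene-disease association data frame with columns `gene` and
#'   `disease_class`.
#' @param min_expected Minimum association count for a class to be reported
#'   (default 5).
#' @return Data frame with columns `disease_class`, `observed`, `expected`
#'   (frequencies) and `ratio`.
#' @export
disease_class_ratios <- function(gene_set, gda, min_expected = 5) {
  stopifnot(all(c("gene", "disease_class") %in% names(gda)))
  if (length(gene_set) == 0L) stop("empty gene set", call. = FALSE)
  if (!all(gene_set %in% gda$gene)) {
    warning("some genes have no association records", call. = FALSE)
  }
  all_tab <- table(gda$disease_class)
  keep <- names(all_tab)[all_tab >= min_expected]
  sub <- gda[gda$gene %in% gene_set, ]
  sub_tab <- table(factor(sub$disease_class, levels = keep))
  expected <- as.numeric(all_tab[keep]) / sum(all_tab)
  observed <- if (nrow(sub) > 0) as.numeric(sub_tab) / nrow(sub) else
    rep(0, length(keep))
  data.frame(disease_class = keep, observed = observed, expected = expected,
             ratio = observed / expected)
}

#' Distribution of a gene set over GTS deciles
#'
#' @param gene_set Character vector of gene identifiers.
#' @param tolerance Gene tolerance table from [gene_tolerance_table()].
#' @return Data frame with one row per decile 0..9: `count` and `frequency`
#'   (frequencies sum to 1 over the scored members of the set).
#' @export
decile_distribution <- function(gene_set, tolerance) {
  stopifnot(all(c("gene", "decile") %in% names(tolerance)))
  scored <- tolerance[tolerance$gene %in% gene_set, ]
  counts <- table(factor(scored$decile, levels = 0:9))
  data.frame(decile = 0:9, count = as.numeric(counts),
             frequency = if (nrow(scored) > 0)
               as.numeric(counts) / nrow(scored) else rep(0, 10))
}

#' Read a gene-disease association TSV (`gene`, `disease`, `disease_class`)
#' @param path Input path.
#' @return Data frame.
#' @export
read_gda_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(gene = "character"))
  stopifnot(all(c("gene", "disease_class") %in% names(df)))
  df
}
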