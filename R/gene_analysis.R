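## Multi-score gene analyses: Z-scoring, correlation-distance
## complete-linkage clustering, and three-way set overlaps.

#' Z-score a gene-by-measure matrix, then center rows
#'
#' Each measure (column) is standardised to mean 0 and sample standard
#' deviation 1 over its non-missing entries; rows are then centered without
#' scaling.  Zero-variance measures are dropped with a warning.
#'
#' @param x Numeric genes x measures matrix (NAs allowed).
#' @param center_rows Apply row centering after column Z-scoring (default
#'   TRUE).
#' @return The transformed matrix.
#' @export
zscore_matrix <- function(x, center_rows = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning("dropping zero-variance measure(s): ",
            paste(colnames(x)[drop], collapse = ", "), call. = FALSE)
    x <- x[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  mus <- colMeans(x, na.rm = TRUE)
  x <- sweep(sweep(x, 2, mus), 2, sds, "/")  # sample-sd standardisation
  if (center_rows) {
    x <- x - rowMeans(x, na.rm = TRUE)
  }
  x
}

#' Cluster genes by complete linkage of correlation distances
#'
#' Distance between two genes is `1 - r` with `r` their Pearson correlation
#' across measures (pairwise-complete over missing values); the dendrogram
#' uses complete linkage, and a flat cut into `k` clusters is returned.
#' Genes with fewer than 2 non-missing measures are excluded with a message.
#'
#' @param x Numeric genes x measures matrix, usually from
#'   [zscore_matrix()]; row names identify genes.
#' @param k Number of flat clusters (default 20, capped at the number of
#'   genes).
#' @return List of class `gene_clustering`: `hclust` (the dendrogram),
#'   `clusters` (named membership vector), `dist` (the distance matrix) and
#'   `excluded` (genes dropped for missingness).
#' @export
cluster_genes <- function(x, k = 20L) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  ok <- rowSums(!is.na(x)) >= 2L
  excluded <- rownames(x)[!ok]
  if (length(excluded) > 0L) {
    message("excluding ", length(excluded),
            " gene(s) with < 2 non-missing measures")
  }
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 genes to cluster", call. = FALSE)
  d <- correlation_distance(x)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  k <- min(k, nrow(x))
  structure(list(hclust = hc, clusters = stats::cutree(hc, k = k),
                 dist = d, excluded = excluded, k = k),
            class = "gene_clustering")
}

#' Correlation distance matrix between rows
#'
#' `d(x, y) = 1 - Pearson r(x, y)` computed with pairwise-complete
#' observations; ranges from 0 (identical up to shift/scale) to 2 (perfectly
#' anti-correlated).
#'
#' @param x Numeric matrix (rows are compared).
#' @return Symmetric distance matrix.
#' @export
correlation_distance <- function(x) {
  r <- stats::cor(t(x), use = "pairwise.complete.obs")
  d <- 1 - r
  d[is.na(d)] <- 2   # undefined correlations treated as maximally distant
  diag(d) <- 0
  d
}

#' Export a gene dendrogram in Newick format
#' @param clustering A [cluster_genes()] result.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat(sprintf("complete-linkage clustering of %d genes (correlation distance)\n",
              length(x$clusters)))
  cat(sprintf("  flat cut: %d clusters; sizes: %s\n", x$k,
              paste(sort(table(x$clusters), decreasing = TRUE),
                    collapse = ", ")))
  invisible(x)
}

#' Three-way set overlap (Venn regions)
#'
#' @param a,b,c Character vectors of gene identifiers.
#' @return Named numeric vector with the 7 region counts: `a_only`,
#'   `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`.
#' @export
set_overlap <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(a, union(b, c))
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  c(a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab = sum(in_a & in_b & !in_c),
    ac = sum(in_a & !in_b & in_c),
    bc = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c))
}
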