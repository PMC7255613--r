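## Shared fixtures, built in code at test time.

## A tiny deterministic alignment: 6 sequences, reference first.
tiny_alignment <- function() {
  sav_alignment(c("ACDEFG",
                  "ACDEFG",
                  "ACDEYG",
                  "ACQEYG",
                  "ACQEFG",
                  "ACDEFG"))
}

## Hand-built gene_data with known profile and annotations.
tiny_gene <- function(gene = "G1", L = 40, seed = 11) {
  set.seed(seed)
  aln <- simulate_alignment(L, n_seqs = 12, conserved_fraction = 0.4,
                            seed = seed, intermediate_fraction = 0.3)
  prof <- estimate_profile(aln)
  ann <- matrix(0, L, length(deepsav_annotation_columns()),
                dimnames = list(NULL, deepsav_annotation_columns()))
  ann[, "H_psipred"] <- 1
  ann[, "ACT_SITE"] <- rep(c(0, 1), length.out = L)
  suppressWarnings(gene_data(gene, prof, ann))
}

## Small proteome + labeled variants for fast model tests.
small_training_set <- function(n_genes = 12, n_per_class = 150, seed = 5) {
  cfg <- sim_config(n_genes = n_genes, length_meanlog = log(120),
                    length_sdlog = 0.2, n_seqs = 20)
  prot <- simulate_proteome(cfg, seed = seed)
  vars <- simulate_labeled_variants(prot, n_per_class, n_per_class,
                                    seed = seed + 1)
  x <- encode_dataset(prot$genes, vars)
  list(proteome = prot, variants = vars, x = x,
       y = as.integer(vars$label == "pathogenic"))
}

## A small network config that trains in seconds; regularisers off so the
## tiny net can fit small planted sets quickly.
tiny_net_config <- function(seed = 1, early_stopping = FALSE, ...) {
  deepsav_config(filters = 16L, dense_units = 16L, epochs = 6L,
                 batch_size = 64L, early_stopping = early_stopping,
                 weight_decay = 0, input_noise = 0, seed = seed, ...)
}

## Brute-force all-pairs AUC oracle.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## Brute-force complete-linkage clustering oracle: returns the merge heights
## and member sets in merge order.
complete_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    }
    merges[[length(merges) + 1L]] <-
      list(height = best[1],
           members = sort(c(clusters[[best[2]]], clusters[[best[3]]])))
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  merges
}
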