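## 90-feature positional encoding and 21-residue model input windows.

#' Assemble per-gene data for feature encoding
#'
#' Bundles the reference sequence, the alignment profile/conservation and the
#' per-position annotation table of one gene.  Missing annotations are imputed
#' as zeros with a warning, never an error.
#'
#' @param gene Gene identifier.
#' @param profile An `sav_profile` from [estimate_profile()].
#' @param annotations Data frame or matrix with one row per reference position
#'   and the 28 columns named in `deepsav_annotation_columns()`; `NULL` imputes
#'   all-zero annotations.
#' @return An object of class `gene_data`.
#' @export
gene_data <- function(gene, profile, annotations = NULL) {
  stopifnot(inherits(profile, "sav_profile"))
  L <- length(profile$positions)
  if (is.null(annotations)) {
    warning("no annotations for gene ", gene, "; imputing zeros",
            call. = FALSE)
    ann <- matrix(0, L, length(ANNOTATION_COLUMNS),
                  dimnames = list(NULL, ANNOTATION_COLUMNS))
  } else {
    annotations <- as.data.frame(annotations)
    missing_cols <- setdiff(ANNOTATION_COLUMNS, names(annotations))
    if (length(missing_cols) > 0L) {
      warning("gene ", gene, ": missing annotation column(s) ",
              paste(missing_cols, collapse = ", "), "; imputing zeros",
              call. = FALSE)
      for (mc in missing_cols) annotations[[mc]] <- 0
    }
    if (nrow(annotations) != L) {
      stop("gene ", gene, ": annotation table has ", nrow(annotations),
           " rows but the protein has ", L, " positions", call. = FALSE)
    }
    ann <- as.matrix(annotations[, ANNOTATION_COLUMNS])
  }
  ## Per-position base feature matrix: wt one-hot + zero mut block + profile +
  ## conservation + annotations + padding 0.  Window extraction then only has
  ## to fill the center mut one-hot and the padding rows.
  base <- matrix(0, L, N_FEATURES, dimnames = list(NULL, FEATURE_NAMES))
  known <- profile$reference %in% AA_ALPHABET
  base[cbind(which(known), aa_index(profile$reference[known]))] <- 1
  base[, 41:60] <- profile$freqs
  base[, 61] <- profile$conservation
  base[, 62:89] <- ann
  structure(list(gene = gene, length = L,
                 reference = profile$reference,
                 profile = profile, annotations = ann, base = base),
            class = "gene_data")
}

#' Annotation column names expected by the encoder
#' @return Character vector of the 28 annotation column names, in encoding
#'   order.
#' @export
deepsav_annotation_columns <- function() ANNOTATION_COLUMNS

#' Feature names of the 90-value positional vector
#' @return Character vector of length 90.
#' @export
deepsav_feature_names <- function() FEATURE_NAMES

#' Encode the 90-feature vector of one position
#'
#' Encodes wild-type and mutant one-hots (40), profile frequencies (20),
#' conservation (1), the 28 annotations, and the padding indicator (0 for any
#' real position).  Neighbour positions inside a window are encoded with their
#' own residue in the wild-type block and an all-zero mutant block; only the
#' window center carries the substitution.
#'
#' @param gd A [gene_data()] object.
#' @param position 1-based position on the reference protein.
#' @param wt Wild-type amino acid; must match the reference residue.
#' @param mut Mutant amino acid, or `NA` for neighbour-style encoding.
#' @return Named numeric vector of length 90.
#' @export
encode_position <- function(gd, position, wt, mut = NA) {
  stopifnot(inherits(gd, "gene_data"))
  if (position < 1L || position > gd$length) {
    stop("position ", position, " outside protein of length ", gd$length,
         call. = FALSE)
  }
  ref <- gd$reference[position]
  if (!is.na(wt) && wt != ref) {
    stop("gene ", gd$gene, " position ", position, ": wild-type ", wt,
         " does not match reference residue ", ref, call. = FALSE)
  }
  if (ref == "X") {
    stop("gene ", gd$gene, " position ", position,
         ": reference residue is 'X'; variant rejected", call. = FALSE)
  }
  v <- gd$base[position, ]
  if (!is.na(mut)) v[20L + aa_index(mut)] <- 1
  v
}

#' Encode the 21 x 90 input window of a variant
#'
#' Builds the model input for one substitution: the variant position plus
#' `half_width` neighbours on each side.  Positions beyond the protein ends
#' are zero-filled with the padding indicator set to 1; the center is never
#' padded.
#'
#' @inheritParams encode_position
#' @param half_width Neighbours on each side (default 10, giving 21 rows).
#' @return A `(2*half_width+1) x 90` matrix of class `feature_window`.
#' @export
encode_window <- function(gd, position, wt, mut, half_width = 10L) {
  center <- encode_position(gd, position, wt, mut)  # validates inputs
  span <- (position - half_width):(position + half_width)
  inside <- span >= 1L & span <= gd$length
  win <- matrix(0, length(span), N_FEATURES,
                dimnames = list(NULL, FEATURE_NAMES))
  win[inside, ] <- gd$base[span[inside], , drop = FALSE]
  win[!inside, N_FEATURES] <- 1
  win[half_width + 1L, ] <- center
  class(win) <- c("feature_window", class(win))
  win
}

#' Flatten a feature window into the 1890-value model input
#' @param window A `feature_window` (21 x 90).
#' @return Numeric vector of length `21 * 90` (position-major).
#' @export
flatten_window <- function(window) as.numeric(t(window))

#' Feature-group ablation mask
#'
#' Named switches for the eight feature groups used in feature-combination
#' and leave-out experiments (e.g. amino-acid types only, all features except
#' the sequence profile).  Disabled groups are zeroed; the padding indicator
#' is never masked.
#'
#' @param AA,profile,conservation,sec.struct,disorder,seg,coiled.coil,uniprotFeat
#'   Logical switches, all `TRUE` by default.
#' @return An object of class `feature_mask`.
#' @export
feature_mask <- function(AA = TRUE, profile = TRUE, conservation = TRUE,
                         sec.struct = TRUE, disorder = TRUE, seg = TRUE,
                         coiled.coil = TRUE, uniprotFeat = TRUE) {
  m <- c(AA = AA, profile = profile, conservation = conservation,
         sec.struct = sec.struct, disorder = disorder, seg = seg,
         coiled.coil = coiled.coil, uniprotFeat = uniprotFeat)
  stopifnot(is.logical(m), !anyNA(m))
  class(m) <- "feature_mask"
  m
}

## Logical length-90 keep vector of a mask.
mask_keep <- function(mask) {
  keep <- rep(TRUE, N_FEATURES)
  for (g in names(FEATURE_GROUPS)) {
    if (!mask[[g]]) keep[FEATURE_GROUPS[[g]]] <- FALSE
  }
  keep  # padding indicator (90) belongs to no group and is always kept
}

#' Apply an ablation mask to a window or encoded matrix
#'
#' @param x A `feature_window` (21 x 90) or an encoded dataset matrix with
#'   `21*90` columns.
#' @param mask A [feature_mask()].
#' @return `x` with disabled feature groups zeroed.
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(mask, "feature_mask"))
  keep <- mask_keep(mask)
  if (inherits(x, "feature_window")) {
    x[, !keep] <- 0
  } else {
    stopifnot(ncol(x) %% N_FEATURES == 0L)
    x[, !rep(keep, ncol(x) / N_FEATURES)] <- 0
  }
  x
}

#' Encode a variant table into a model input matrix
#'
#' @param genes Named list of [gene_data()] objects.
#' @param variants Data frame with columns `gene`, `position`, `wt`, `mut`.
#' @param mask Optional [feature_mask()] applied after encoding.
#' @param half_width Window half-width (default 10).
#' @return Numeric matrix with one row per variant and `90 * (2*half_width+1)`
#'   columns.
#' @export
encode_dataset <- function(genes, variants, mask = NULL, half_width = 10L) {
  stopifnot(all(c("gene", "position", "wt", "mut") %in% names(variants)))
  missing_genes <- setdiff(unique(variants$gene), names(genes))
  if (length(missing_genes) > 0L) {
    stop("no gene data for: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(variants)
  X <- matrix(0, n, N_FEATURES * (2L * half_width + 1L))
  for (i in seq_len(n)) {
    X[i, ] <- flatten_window(encode_window(
      genes[[variants$gene[i]]], variants$position[i],
      variants$wt[i], variants$mut[i], half_width = half_width))
  }
  if (!is.null(mask)) X <- apply_mask(X, mask)
  X
}

#' Read a variant TSV
#'
#' Expected columns: `gene`, `position`, `wt`, `mut`, optionally `maf` and
#' `label` (`pathogenic`/`benign`), optionally `deepsav_score`.
#'
#' @param path Input path.
#' @return Data frame of variants.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(gene = "character"))
  need <- c("gene", "position", "wt", "mut")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("variant table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if ("label" %in% names(df)) {
    bad <- setdiff(unique(df$label), c("pathogenic", "benign"))
    if (length(bad) > 0L) {
      stop("unknown label(s) in ", path, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  df
}

#' Write a variant TSV
#' @param variants Data frame of variants.
#' @param path Output path.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a per-position annotation TSV
#'
#' Expected columns: `gene`, `position`, then the 28 annotation columns named
#' in `deepsav_annotation_columns()` (header required, 1-based positions).
#'
#' @param path Input path.
#' @return Named list of per-gene annotation data frames ordered by position.
#' @export
read_annotations_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(gene = "character"))
  stopifnot(all(c("gene", "position") %in% names(df)))
  split_df <- split(df, df$gene)
  lapply(split_df, function(d) d[order(d$position), , drop = FALSE])
}

#' Write per-gene annotations as one TSV
#' @param annotations Named list of per-gene annotation data frames (as built
#'   by the simulator), each with a `position` column plus the 28 annotation
#'   columns.
#' @param path Output path.
#' @export
write_annotations_tsv <- function(annotations, path) {
  rows <- lapply(names(annotations), function(g) {
    d <- as.data.frame(annotations[[g]])
    if (!"position" %in% names(d)) d$position <- seq_len(nrow(d))
    cbind(gene = g, d[, c("position", ANNOTATION_COLUMNS)])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read the 17-column gene-level feature table (dbNSFP-style)
#' @param path Input path; columns `gene` plus the 17 features.
#' @return Data frame with one row per gene.
#' @export
read_gene_features_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(gene = "character"))
  miss <- setdiff(c("gene", GENE_FEATURE_COLUMNS), names(df))
  if (length(miss) > 0L) {
    stop("gene feature table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a gene-length TSV (`gene`, `protein_len`)
#' @param path Input path.
#' @return Data frame.
#' @export
read_gene_lengths_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(gene = "character"))
  stopifnot(all(c("gene", "protein_len") %in% names(df)))
  df
}
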