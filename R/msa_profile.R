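## Alignment profiles, conservation and the baseline fitness score.

#' Construct an ortholog alignment object
#'
#' An alignment is a set of equal-length gapped amino-acid sequences with one
#' designated reference (typically the human sequence).  Positions elsewhere in
#' the package are 1-based indices on the ungapped reference.
#'
#' @param sequences Character vector of aligned sequences (gap character `-`).
#' @param reference_index Index of the reference sequence (default 1).
#' @param names Optional sequence names.
#' @return An object of class `sav_alignment`.
#' @export
sav_alignment <- function(sequences, reference_index = 1L, names = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 2L) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  if (widths[1] == 0L) stop("empty alignment", call. = FALSE)
  if (reference_index < 1L || reference_index > length(sequences)) {
    stop("reference_index out of range", call. = FALSE)
  }
  ref_chars <- strsplit(sequences[reference_index], "")[[1]]
  bad <- setdiff(unique(ref_chars), c(AA_ALPHABET, "X", "-"))
  if (length(bad) > 0L) {
    stop("reference sequence contains unknown symbols: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(sequences = sequences,
                 reference_index = as.integer(reference_index),
                 names = names,
                 column_count = widths[1]),
            class = "sav_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @param reference Name or index of the reference sequence; defaults to the
#'   first record.
#' @return A [sav_alignment()] object.
#' @export
read_alignment <- function(path, reference = 1L) {
  aln <- Biostrings::readBStringSet(path)
  if (is.character(reference)) {
    reference <- match(reference, names(aln))
    if (is.na(reference)) stop("reference sequence not found in ", path,
                               call. = FALSE)
  }
  sav_alignment(as.character(aln), reference_index = reference,
                names = names(aln))
}

#' Write an alignment as FASTA
#'
#' @param alignment A [sav_alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  nm <- alignment$names
  if (is.null(nm)) nm <- paste0("seq", seq_along(alignment$sequences))
  x <- Biostrings::BStringSet(alignment$sequences)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path)
}

## Character matrix (n_seq x n_col) of an alignment.
alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$sequences, ""))
}

## 1-based alignment-column index for each ungapped reference position.
reference_columns <- function(alignment) {
  ref <- strsplit(alignment$sequences[alignment$reference_index], "")[[1]]
  which(ref != "-")
}

#' Ungapped reference sequence of an alignment
#' @param alignment A [sav_alignment()].
#' @return Character vector of reference residues (may include `X`).
#' @export
reference_sequence <- function(alignment) {
  ref <- strsplit(alignment$sequences[alignment$reference_index], "")[[1]]
  ref[ref != "-"]
}

## Henikoff position-based sequence weights.  For each column, a residue r in
## that column contributes 1/(k * n_r) to its sequence, where k is the number
## of distinct residues in the column and n_r the count of residue r; weights
## are the per-sequence means over columns and normalised to sum to n_seq.
henikoff_weights <- function(mat) {
  n_seq <- nrow(mat)
  w <- numeric(n_seq)
  n_used <- numeric(n_seq)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    ok <- col %in% AA_ALPHABET
    if (!any(ok)) next
    tab <- table(col[ok])
    k <- length(tab)
    contrib <- 1 / (k * as.numeric(tab[col[ok]]))
    w[ok] <- w[ok] + contrib
    n_used[ok] <- n_used[ok] + 1
  }
  w <- ifelse(n_used > 0, w / n_used, 0)
  if (sum(w) == 0) w[] <- 1
  w * n_seq / sum(w)
}

#' Estimate per-position amino-acid profiles and conservation
#'
#' Computes, for every ungapped reference position, the estimated amino-acid
#' frequency vector (gap and `X` symbols excluded from counts, uniform
#' pseudocount added) and the normalised-entropy conservation score.
#'
#' @param alignment A [sav_alignment()].
#' @param pseudocount Non-negative pseudocount added per amino acid before
#'   normalisation (default 0.05).
#' @param weighting `"none"` (default) or `"henikoff"` position-based sequence
#'   weighting.
#' @return A list of class `sav_profile` with elements `freqs` (L x 20 matrix,
#'   rows summing to 1), `conservation` (length-L vector in `[0,1]`),
#'   `reference` (length-L residue vector) and `positions` (1-based).
#' @export
estimate_profile <- function(alignment, pseudocount = 0.05,
                             weighting = c("none", "henikoff")) {
  weighting <- match.arg(weighting)
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  mat <- alignment_matrix(alignment)
  cols <- reference_columns(alignment)
  if (length(cols) == 0L) stop("reference sequence is all gaps", call. = FALSE)
  w <- if (weighting == "henikoff") henikoff_weights(mat) else
    rep(1, nrow(mat))

  L <- length(cols)
  idxmat <- matrix(match(mat[, cols, drop = FALSE], AA_ALPHABET),
                   nrow = nrow(mat))
  freqs <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  consv <- numeric(L)
  uniform_w <- weighting == "none"
  for (i in seq_len(L)) {
    v <- idxmat[, i]
    ok <- !is.na(v)
    counts <- if (uniform_w) {
      tabulate(v[ok], nbins = 20L)
    } else {
      vapply(1:20, function(a) sum(w[ok][v[ok] == a]), numeric(1))
    }
    tot <- sum(counts) + 20 * pseudocount
    if (tot == 0) {
      stop("column ", cols[i],
           " has no countable residues and pseudocount is 0", call. = FALSE)
    }
    freqs[i, ] <- (counts + pseudocount) / tot
    ## conservation from unweighted observed frequencies, no pseudocount
    nobs <- tabulate(v[ok], nbins = 20L)
    if (sum(nobs) == 0) {
      stop("column ", cols[i], " has no standard residues", call. = FALSE)
    }
    p <- nobs[nobs > 0] / sum(nobs)
    consv[i] <- max(0, min(1, 1 + sum(p * log(p)) / log(20)))
  }
  structure(list(freqs = freqs, conservation = consv,
                 reference = reference_sequence(alignment),
                 positions = seq_len(L)),
            class = "sav_profile")
}

#' Normalised-entropy conservation score of an alignment column
#'
#' Returns `1 - H / log(20)` where `H` is the Shannon entropy of the observed
#' (gap- and `X`-excluded) residue frequencies: 1 for an invariant column, 0
#' for a column uniform over all 20 amino acids.
#'
#' @param residues Character vector of residues observed in one column; gaps
#'   and non-standard symbols are ignored.
#' @return Conservation score in `[0, 1]`.
#' @export
conservation_score <- function(residues) {
  residues <- residues[residues %in% AA_ALPHABET]
  if (length(residues) == 0L) {
    stop("column has no standard residues", call. = FALSE)
  }
  p <- tabulate(match(residues, AA_ALPHABET), nbins = 20L)
  p <- p / sum(p)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  max(0, min(1, 1 - h / log(20)))
}

#' Bin a conservation score into the three conservation classes
#'
#' Low conservation (`[0, 0.3)`) is `Consv1`, medium (`[0.3, 0.6]`) `Consv2`,
#' and high (`> 0.6`) `Consv3`.
#'
#' @param score Numeric vector of conservation scores in `[0, 1]`.
#' @return Character vector of bin labels.
#' @export
bin_conservation <- function(score) {
  if (any(score < 0 | score > 1 | is.na(score))) {
    stop("conservation scores must lie in [0, 1]", call. = FALSE)
  }
  ifelse(score < 0.3, "Consv1", ifelse(score <= 0.6, "Consv2", "Consv3"))
}

#' Baseline fitness score of a substitution
#'
#' Profile log-odds between the wild-type and mutant amino-acid frequencies,
#' `log2((f_wt + eps) / (f_mut + eps))`.  Larger values indicate a more severe
#' substitution; the score is antisymmetric under swapping `wt` and `mut`.
#'
#' @param freqs Length-20 frequency vector (one profile column), or an
#'   `sav_profile` together with `position`.
#' @param wt,mut Single-letter wild-type and mutant amino acids.
#' @param position 1-based reference position when `freqs` is an
#'   `sav_profile`.
#' @param epsilon Small positive regulariser added to both frequencies
#'   (default 1e-4).
#' @return Numeric log2 odds score.
#' @export
baseline_fitness <- function(freqs, wt, mut, position = NULL,
                             epsilon = 1e-4) {
  if (inherits(freqs, "sav_profile")) {
    stopifnot(!is.null(position))
    freqs <- freqs$freqs[position, ]
  }
  if (wt == mut) stop("wt and mut must differ", call. = FALSE)
  i <- aa_index(wt); j <- aa_index(mut)
  log2((freqs[[i]] + epsilon) / (freqs[[j]] + epsilon))
}

#' Write a per-position profile/conservation table as TSV
#'
#' Columns: gene, position, one frequency column per amino acid, conservation.
#'
#' @param profile An `sav_profile`.
#' @param gene Gene identifier to stamp on every row.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, gene, path) {
  df <- data.frame(gene = gene, position = profile$positions,
                   profile$freqs, conservation = profile$conservation,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-position profile/conservation TSV written by
#' [write_profile_tsv()]
#' @param path Input path.
#' @return A data.frame.
#' @export
read_profile_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
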