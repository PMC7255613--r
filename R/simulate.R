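## Synthetic-data generator: alignments with a conservation gradient,
## structural/functional annotation tables, labeled variant sets with a
## planted pathogenicity signal, and a rare-dominated allele-frequency
## catalog.  Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults define the package's standard synthetic study conditions: 120
#' genes with log-normal protein lengths (median ~400 aa), 50-sequence
#' ortholog alignments with 30% invariant, 40% partially conserved and 30%
#' unconstrained columns, annotation base rates of 0.08 for the binary
#' UniProt-style flags, pathogenic planting odds taken from the qualitative
#' enrichment directions of real pathogenic variants (strong enrichment at
#' functional/stability sites, ~2-fold at transmembrane segments, depletion
#' in disordered regions), and an allele-frequency spectrum dominated by rare
#' variants (93.9% / 4.4% / 1.1% / 0.57% across the four MAF categories).
#'
#' @param n_genes Number of genes.
#' @param length_meanlog,length_sdlog,length_min,length_max Log-normal
#'   protein-length distribution (amino acids).
#' @param n_seqs Sequences per ortholog alignment.
#' @param conserved_fraction Fraction of invariant alignment columns.
#' @param intermediate_fraction Fraction of partially conserved columns (a
#'   small favoured residue subset); the remainder is unconstrained.
#' @param flag_rate Base rate of the binary annotation flags.
#' @param disorder_fraction Fraction of the protein inside disordered
#'   segments.
#' @param property_odds Named fold-enrichment of annotation properties among
#'   pathogenic variant positions (values < 1 deplete).  Disorder planting
#'   uses the binarised (>= 0.5) propensity columns.
#' @param conservation_beta_pathogenic,conservation_beta_benign Exponential
#'   tilt of position sampling with conservation for each class.
#' @param wt_aa_odds Named per-residue odds applied to the wild-type amino
#'   acid of pathogenic positions (the amino-acid-only signal).
#' @param maf_weights Category weights (rare, low, medium, common) of the
#'   allele-frequency spectrum; normalised internally.
#' @param maf_weights_pathogenic Spectrum used for pathogenic labeled
#'   variants (almost entirely rare).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 120L,
                       length_meanlog = log(400), length_sdlog = 0.35,
                       length_min = 80L, length_max = 1500L,
                       n_seqs = 50L,
                       conserved_fraction = 0.30,
                       intermediate_fraction = 0.40,
                       flag_rate = 0.08,
                       disorder_fraction = 0.20,
                       property_odds = c(ACT_SITE = 4, DISULFID = 4,
                                         METAL = 4, BINDING = 4, SITE = 4,
                                         MOTIF = 2, TRANSMEM = 2,
                                         disopred = 0.5, spotd = 0.5,
                                         iupred2a = 0.5),
                       conservation_beta_pathogenic = 2.5,
                       conservation_beta_benign = -2.5,
                       wt_aa_odds = c(C = 2, W = 2, G = 1.5, P = 1.5),
                       maf_weights = c(rare = 0.9393, low = 0.0440,
                                       medium = 0.0110, common = 0.0057),
                       maf_weights_pathogenic = c(rare = 0.995, low = 0.004,
                                                  medium = 0.0009,
                                                  common = 0.0001)) {
  stopifnot(n_genes >= 1, n_seqs >= 2,
            conserved_fraction >= 0, intermediate_fraction >= 0,
            conserved_fraction + intermediate_fraction <= 1,
            flag_rate >= 0, flag_rate <= 1, all(property_odds > 0),
            all(maf_weights >= 0))
  structure(list(n_genes = as.integer(n_genes),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 n_seqs = as.integer(n_seqs),
                 conserved_fraction = conserved_fraction,
                 intermediate_fraction = intermediate_fraction,
                 flag_rate = flag_rate,
                 disorder_fraction = disorder_fraction,
                 property_odds = property_odds,
                 conservation_beta_pathogenic = conservation_beta_pathogenic,
                 conservation_beta_benign = conservation_beta_benign,
                 wt_aa_odds = wt_aa_odds,
                 maf_weights = maf_weights / sum(maf_weights),
                 maf_weights_pathogenic =
                   maf_weights_pathogenic / sum(maf_weights_pathogenic)),
            class = "sim_config")
}

#' Neutral planting settings for null simulations
#'
#' Returns `config` with all property odds at 1, conservation tilts at 0 and
#' wild-type amino-acid odds at 1, so variant positions are sampled
#' uniformly.
#'
#' @param config A [sim_config()].
#' @return A `sim_config` with neutral planting.
#' @export
neutral_planting <- function(config = sim_config()) {
  config$property_odds[] <- 1
  config$conservation_beta_pathogenic <- 0
  config$conservation_beta_benign <- 0
  config$wt_aa_odds[] <- 1
  config
}

#' Simulate an ortholog alignment
#'
#' Invariant columns repeat one residue; partially conserved columns draw
#' from a small favoured residue subset (frequencies 0.4/0.3/0.2/0.1);
#' unconstrained columns draw uniformly from the 20 amino acids.  The first
#' sequence is the reference; the alignment is gap-free.
#'
#' @param length Number of columns (protein length).
#' @param n_seqs Number of sequences (>= 2).
#' @param conserved_fraction Fraction of invariant columns.
#' @param seed Integer seed.
#' @param intermediate_fraction Fraction of partially conserved columns
#'   (default 0).
#' @return A [sav_alignment()].
#' @export
simulate_alignment <- function(length, n_seqs = 50L, conserved_fraction = 0.3,
                               seed = 1L, intermediate_fraction = 0) {
  stopifnot(length >= 1, n_seqs >= 2,
            conserved_fraction + intermediate_fraction <= 1)
  set.seed(seed)
  kind <- sample(c("consv", "inter", "flat"), length, replace = TRUE,
                 prob = c(conserved_fraction, intermediate_fraction,
                          1 - conserved_fraction - intermediate_fraction))
  mat <- matrix("", n_seqs, length)
  for (j in seq_len(length)) {
    mat[, j] <- switch(
      kind[j],
      consv = rep(sample(AA_ALPHABET, 1L), n_seqs),
      inter = sample(sample(AA_ALPHABET, 4L), n_seqs, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
      flat = sample(AA_ALPHABET, n_seqs, replace = TRUE))
  }
  sav_alignment(apply(mat, 1, paste, collapse = ""),
                names = c("reference", paste0("ortholog", seq_len(n_seqs - 1L))))
}

## Block-structured binary track: segments of mean length `block_len` covering
## about `rate` of the protein.
sim_blocks <- function(L, rate, block_len) {
  x <- numeric(L)
  n_blocks <- stats::rpois(1, L * rate / block_len)
  if (n_blocks > 0) {
    starts <- sample.int(L, n_blocks, replace = TRUE)
    lens <- pmax(2L, stats::rpois(n_blocks, block_len))
    for (b in seq_len(n_blocks)) {
      x[starts[b]:min(L, starts[b] + lens[b] - 1L)] <- 1
    }
  }
  x
}

## Run-structured 3-state secondary structure, one-hot for three predictors
## that disagree with the underlying state 10% of the time.
sim_secondary_structure <- function(L) {
  states <- character(0)
  while (length(states) < L) {
    s <- sample(c("H", "E", "C"), 1, prob = c(0.35, 0.2, 0.45))
    states <- c(states, rep(s, 1 + stats::rgeom(1, 1 / 8)))
  }
  states <- states[seq_len(L)]
  out <- matrix(0, L, 9L)
  for (p in 1:3) {
    pred <- states
    flip <- stats::runif(L) < 0.1
    pred[flip] <- sample(c("H", "E", "C"), sum(flip), replace = TRUE)
    out[cbind(seq_len(L), (p - 1L) * 3L + match(pred, c("H", "E", "C")))] <- 1
  }
  out
}

## Per-position annotation table of one gene (the 28 encoder columns).
simulate_annotations <- function(L, config) {
  ann <- matrix(0, L, length(ANNOTATION_COLUMNS),
                dimnames = list(NULL, ANNOTATION_COLUMNS))
  ann[, 1:9] <- sim_secondary_structure(L)
  ## disorder propensity: disordered segments high, ordered background low;
  ## three predictors share the base signal with independent noise
  base <- 0.2 + 0.6 * sim_blocks(L, config$disorder_fraction, 30)
  for (p in 1:3) {
    ann[, 9L + p] <- pmin(1, pmax(0, base + stats::rnorm(L, 0, 0.08)))
  }
  ann[, "seg"] <- sim_blocks(L, config$flag_rate, 10)
  ann[, "ncoil"] <- sim_blocks(L, config$flag_rate, 25)
  ## one N-terminal targeting peptide per gene at most
  targeting <- sample(c("SIGNAL", "TRANSIT", "none"), 1,
                      prob = c(0.5, 0.35, 0.15))
  if (targeting != "none") {
    len <- min(L, sample(25:50, 1))
    ann[seq_len(len), targeting] <- 1
  }
  ann[, "TRANSMEM"] <- sim_blocks(L, config$flag_rate, 21)
  for (col in c("P_MODRES", "A_MODRES", "M_MODRES", "DISULFID", "CARBOHYD",
                "METAL", "BINDING", "ACT_SITE", "SITE", "LIPID", "MOTIF")) {
    ann[, col] <- stats::rbinom(L, 1, config$flag_rate)
  }
  ann
}

#' Simulate a synthetic proteome
#'
#' Generates `n_genes` genes: an ortholog alignment each (conservation
#' gradient per [simulate_alignment()]), the derived profile/conservation,
#' and a per-position annotation table, bundled as [gene_data()] objects.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_proteome` with elements `genes` (named list
#'   of `gene_data`), `alignments`, `annotations`, `lengths` (data frame) and
#'   `config`.
#' @export
simulate_proteome <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  lens <- pmin(config$length_max,
               pmax(config$length_min,
                    round(stats::rlnorm(config$n_genes, config$length_meanlog,
                                        config$length_sdlog))))
  aln_seeds <- sample.int(.Machine$integer.max, config$n_genes)
  ann_seeds <- sample.int(.Machine$integer.max, config$n_genes)
  genes <- alignments <- annotations <-
    stats::setNames(vector("list", config$n_genes), gene_ids)
  for (i in seq_len(config$n_genes)) {
    aln <- simulate_alignment(lens[i], config$n_seqs,
                              config$conserved_fraction, seed = aln_seeds[i],
                              intermediate_fraction =
                                config$intermediate_fraction)
    prof <- estimate_profile(aln)
    set.seed(ann_seeds[i])
    ann <- simulate_annotations(lens[i], config)
    alignments[[i]] <- aln
    annotations[[i]] <- ann
    genes[[i]] <- gene_data(gene_ids[i], prof, ann)
  }
  structure(list(genes = genes, alignments = alignments,
                 annotations = annotations,
                 lengths = data.frame(gene = gene_ids, protein_len = lens),
                 config = config),
            class = "sim_proteome")
}

#' Per-position binarised property table of a proteome
#'
#' One row per (gene, position) with the three conservation-bin indicators
#' and the 28 annotation columns binarised at 0.5 (one-hot and flag columns
#' are unchanged by this; disorder propensities become ordered/disordered
#' calls).
#'
#' @param proteome A [simulate_proteome()] result, or any named list of
#'   `gene_data`.
#' @return Data frame with columns `gene`, `position`, `Consv1`, `Consv2`,
#'   `Consv3` and the 28 annotation columns.
#' @export
position_property_table <- function(proteome) {
  genes <- if (inherits(proteome, "sim_proteome")) proteome$genes else
    proteome
  rows <- lapply(genes, function(gd) {
    bin <- bin_conservation(gd$profile$conservation)
    data.frame(gene = gd$gene, position = seq_len(gd$length),
               Consv1 = as.numeric(bin == "Consv1"),
               Consv2 = as.numeric(bin == "Consv2"),
               Consv3 = as.numeric(bin == "Consv3"),
               (gd$annotations >= 0.5) * 1, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Sampling weight per position for one class.  Property odds are target
## fold-changes of the realised unique-position frequency in a subset of
## size n drawn without replacement.  Because inclusion probabilities
## saturate (1 - exp(-t*w)), the per-property weight multipliers are solved
## by fixed-point iteration against the expected inclusion probabilities so
## that each property's expected subset frequency is exactly o * r.
planting_weights <- function(ptab, wt_res, beta, property_odds, wt_aa_odds,
                             n_draw = NULL) {
  base <- exp(beta * ptab$consv)
  if (length(wt_aa_odds) > 0) {
    m <- wt_aa_odds[wt_res]
    m[is.na(m)] <- 1
    base <- base * m
  }
  base[wt_res == "X"] <- 0
  odds <- property_odds[property_odds != 1]
  odds <- odds[names(odds) %in% names(ptab)]
  if (length(odds) == 0L) return(base)

  flags <- as.matrix(ptab[, names(odds), drop = FALSE])
  rates <- colMeans(flags)
  use <- rates > 0 & rates < 1 & odds * rates < 1
  odds <- odds[use]
  flags <- flags[, use, drop = FALSE]
  rates <- rates[use]
  if (length(odds) == 0L) return(base)

  wp <- odds * (1 - rates) / (1 - odds * rates)  # no-saturation solution
  if (is.null(n_draw)) n_draw <- max(1, round(0.05 * nrow(flags)))
  n_draw <- min(n_draw, sum(base > 0) - 1)
  for (iter in 1:25) {
    w <- base * exp(flags %*% log(wp))[, 1]
    ## expected inclusion probabilities of a weighted draw of n_draw items
    tt <- stats::uniroot(function(t) sum(1 - exp(-t * w)) - n_draw,
                         lower = 0, upper = 1e6, tol = 1e-10)$root
    incl <- 1 - exp(-tt * w)
    realised <- colSums(flags * incl) / sum(incl)
    target <- odds * rates
    if (max(abs(realised / target - 1)) < 1e-3) break
    wp <- wp * target / realised
  }
  base * exp(flags %*% log(wp))[, 1]
}

#' Simulate a labeled variant set with planted pathogenicity signal
#'
#' Pathogenic variants are preferentially placed at conserved and annotated
#' positions (per the configured planting odds) and mutate towards residues
#' that are rare in the position's profile; benign variants favour variable
#' positions and profile-compatible residues.  Minor allele frequencies are
#' drawn from the class-specific spectra.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param n_pathogenic,n_benign Requested counts (default 4000 each,
#'   class-balanced).
#' @param config A [sim_config()]; defaults to the proteome's.
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `position`, `wt`, `mut`, `maf`,
#'   `label`.
#' @export
simulate_labeled_variants <- function(proteome, n_pathogenic = 4000L,
                                      n_benign = 4000L,
                                      config = proteome$config, seed = 1L) {
  set.seed(seed)
  ptab <- proteome_position_info(proteome)
  n_pos <- nrow(ptab)
  if (n_pathogenic + n_benign > 19L * n_pos) {
    stop("requested counts exceed available substitutions", call. = FALSE)
  }
  w_path <- planting_weights(ptab, ptab$wt,
                             config$conservation_beta_pathogenic,
                             config$property_odds, config$wt_aa_odds,
                             n_draw = n_pathogenic)
  w_ben <- planting_weights(ptab, ptab$wt,
                            config$conservation_beta_benign,
                            stats::setNames(rep(1, 0), character(0)),
                            numeric(0))
  path <- sample_variants(proteome, ptab, w_path, n_pathogenic,
                          mut_mode = "pathogenic", taken = character(0))
  ben <- sample_variants(proteome, ptab, w_ben, n_benign,
                         mut_mode = "benign",
                         taken = variant_key(path))
  path$maf <- draw_mafs(sample(names(config$maf_weights_pathogenic),
                               nrow(path), replace = TRUE,
                               prob = config$maf_weights_pathogenic))
  ben$maf <- draw_mafs(sample(names(config$maf_weights), nrow(ben),
                              replace = TRUE, prob = config$maf_weights))
  path$label <- "pathogenic"
  ben$label <- "benign"
  out <- rbind(path, ben)
  rownames(out) <- NULL
  out
}

## Flat per-position lookup across a proteome: gene, position, wt residue,
## conservation, binarised properties, and row index of the profile.
proteome_position_info <- function(proteome) {
  ptab <- position_property_table(proteome)
  wt <- unlist(lapply(proteome$genes, function(gd) gd$reference),
               use.names = FALSE)
  data.frame(ptab[, c("gene", "position")], wt = wt,
             consv = unlist(lapply(proteome$genes,
                                   function(gd) gd$profile$conservation),
                            use.names = FALSE),
             ptab[, setdiff(names(ptab), c("gene", "position"))],
             check.names = FALSE)
}

variant_key <- function(v) paste(v$gene, v$position, v$mut)

## Draw `n` distinct variants using position weights `w`.  Positions are
## sampled WITHOUT replacement (one substitution per drawn position) so the
## unique-position frequency of a planted property matches its calibrated
## target.  Mutant residues are sampled from the position profile (benign:
## proportional to f + 0.02; pathogenic: proportional to 1/(f + 0.05)); the
## rare substitution that collides with an already-taken (gene, position,
## mutant) triple is re-drawn from the remaining residues.
sample_variants <- function(proteome, ptab, w, n, mut_mode, taken) {
  avail <- sum(w > 0)
  if (n > avail) {
    stop("requested counts exceed available positions", call. = FALSE)
  }
  draw <- sample.int(nrow(ptab), n, replace = FALSE, prob = w)
  muts <- character(n)
  for (j in seq_len(n)) {
    i <- draw[j]
    gd <- proteome$genes[[ptab$gene[i]]]
    f <- gd$profile$freqs[ptab$position[i], ]
    p <- if (mut_mode == "pathogenic") 1 / (f + 0.05) else f + 0.02
    p[aa_index(ptab$wt[i])] <- 0
    m <- sample(AA_ALPHABET, 1L, prob = p)
    if (paste(ptab$gene[i], ptab$position[i], m) %in% taken) {
      p[aa_index(m)] <- 0
      m <- sample(AA_ALPHABET, 1L, prob = p)
    }
    muts[j] <- m
  }
  data.frame(gene = ptab$gene[draw], position = ptab$position[draw],
             wt = ptab$wt[draw], mut = muts)
}

## Log-uniform MAF inside each category band.
draw_mafs <- function(category) {
  lo <- c(rare = 1e-6, low = 1e-4, medium = 1e-3, common = 1e-2)[category]
  hi <- c(rare = 1e-4, low = 1e-3, medium = 1e-2, common = 0.5)[category]
  exp(stats::runif(length(category), log(lo), log(hi)))
}

#' Simulate a gnomAD-like variant catalog
#'
#' Variants are placed uniformly over positions and non-wild-type residues;
#' minor allele frequencies follow the configured four-category spectrum
#' (rare-dominated by default) with log-uniform values inside each band.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param n_variants Catalog size.
#' @param weights Category weights (rare, low, medium, common); defaults to
#'   the proteome config's spectrum.
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `position`, `wt`, `mut`, `maf`.
#' @export
simulate_maf_catalog <- function(proteome, n_variants = 100000L,
                                 weights = proteome$config$maf_weights,
                                 seed = 1L) {
  set.seed(seed)
  weights <- weights / sum(weights)
  ptab <- proteome_position_info(proteome)
  ok <- which(ptab$wt != "X")
  draw <- sample(ok, n_variants, replace = TRUE)
  wt_idx <- aa_index(ptab$wt[draw])
  mut_idx <- (wt_idx - 1L + sample.int(19L, n_variants, replace = TRUE)) %% 20L + 1L
  out <- data.frame(gene = ptab$gene[draw], position = ptab$position[draw],
                    wt = ptab$wt[draw], mut = AA_ALPHABET[mut_idx])
  ## de-duplicate substitutions before assigning frequencies so the category
  ## shares stay unbiased; the catalog may therefore be slightly smaller than
  ## n_variants
  out <- out[!duplicated(variant_key(out)), , drop = FALSE]
  cat_draw <- sample(names(weights), nrow(out), replace = TRUE,
                     prob = weights)
  out$maf <- draw_mafs(cat_draw)
  rownames(out) <- NULL
  out
}

#' Simulate a 17-column gene-level feature table
#'
#' dbNSFP-style per-gene features: protein-interaction counts, essentiality
#' screens, haploinsufficiency/indispensability scores, P(rec), GDI-Phred,
#' LoFtool and the pLI/pRec/pNull triple.  A latent per-gene constraint value
#' correlates the score-type columns, as in real gene-level annotation.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param seed Integer seed.
#' @return Data frame with column `gene` plus the 17 feature columns.
#' @export
simulate_gene_features <- function(gene_ids, seed = 1L) {
  set.seed(seed)
  n <- length(gene_ids)
  constraint <- stats::rnorm(n)           # latent intolerance
  sig <- function(x) 1 / (1 + exp(-x))
  noisy <- function(s = 1) constraint + stats::rnorm(n, 0, s)
  pli_raw <- exp(noisy(0.7)); prec_raw <- exp(stats::rnorm(n))
  pnull_raw <- exp(-noisy(0.7))
  tot <- pli_raw + prec_raw + pnull_raw
  data.frame(
    gene = gene_ids,
    ppi_intact = stats::rnbinom(n, mu = 20 * exp(0.3 * constraint), size = 2),
    ppi_biogrid = stats::rnbinom(n, mu = 40 * exp(0.3 * constraint), size = 2),
    ppi_cpdb = stats::rnbinom(n, mu = 60 * exp(0.3 * constraint), size = 2),
    ess_crispr1 = as.numeric(sig(noisy()) > 0.7),
    ess_crispr2 = as.numeric(sig(noisy()) > 0.7),
    ess_trap = sig(noisy()),
    ess_blomen = sig(noisy()),
    p_hi = sig(noisy(0.8)),
    hipred = sig(noisy(0.8)),
    ghis = sig(noisy(0.8)),
    gene_indispensability = sig(noisy(0.8)),
    p_rec = sig(stats::rnorm(n)),
    gdi_phred = stats::rgamma(n, shape = 3, rate = 1 / 4),
    loftool = sig(-noisy(0.8)),
    pli = pli_raw / tot,
    prec_lof = prec_raw / tot,
    pnull = pnull_raw / tot)
}

#' Write a complete synthetic fixture directory
#'
#' Emits the on-disk artifact set the pipeline consumes: one aligned FASTA
#' per gene under `alignments/`, `annotations.tsv`, `variants.tsv` (labeled),
#' `catalog.tsv` (MAF catalog, if given), `gene_lengths.tsv` and
#' `gene_features.tsv`.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param dir Output directory (created).
#' @param variants Optional labeled variant data frame.
#' @param catalog Optional MAF catalog data frame.
#' @param gene_features Optional gene-level feature table.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(proteome, dir, variants = NULL, catalog = NULL,
                              gene_features = NULL) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in names(proteome$alignments)) {
    write_alignment(proteome$alignments[[g]],
                    file.path(dir, "alignments", paste0(g, ".fasta")))
  }
  write_annotations_tsv(proteome$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(proteome$lengths, file.path(dir, "gene_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(variants)) {
    write_variants_tsv(variants, file.path(dir, "variants.tsv"))
  }
  if (!is.null(catalog)) {
    write_variants_tsv(catalog, file.path(dir, "catalog.tsv"))
  }
  if (!is.null(gene_features)) {
    utils::write.table(gene_features, file.path(dir, "gene_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
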