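#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids in a fixed alphabetical (one-letter) order.
## All one-hot blocks, profile columns and substitution lookups use this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Per-position annotation columns consumed from the annotation table, in the
## fixed order they occupy inside the 90-feature vector.  Three 3-state
## secondary-structure predictors (helix/strand/coil each), three disorder
## propensity predictors, low-complexity (seg) and coiled-coil (ncoil) flags,
## subcellular-targeting regions, three MOD_RES modification types, and the
## remaining UniProt Feature keywords.
ANNOTATION_COLUMNS <- c(
  "H_psipred", "E_psipred", "C_psipred",
  "H_spd3",    "E_spd3",    "C_spd3",
  "H_predss",  "E_predss",  "C_predss",
  "disopred",  "spotd",     "iupred2a",
  "seg",       "ncoil",
  "SIGNAL",    "TRANSIT",   "TRANSMEM",
  "P_MODRES",  "A_MODRES",  "M_MODRES",
  "DISULFID",  "CARBOHYD",  "METAL",     "BINDING",
  "ACT_SITE",  "SITE",      "LIPID",     "MOTIF")

## Layout of the 90-value per-position feature vector:
##   1-20   wild-type amino acid one-hot
##   21-40  mutant amino acid one-hot (zero except at the window center)
##   41-60  profile amino-acid frequencies
##   61     conservation score
##   62-89  the 28 annotation columns above
##   90     zero-padding indicator
N_FEATURES <- 90L
WINDOW_SIZE <- 21L

FEATURE_NAMES <- c(
  paste0("wt_", AA_ALPHABET),
  paste0("mut_", AA_ALPHABET),
  paste0("prof_", AA_ALPHABET),
  "conservation",
  ANNOTATION_COLUMNS,
  "padding")

## Feature-group index map used by ablation masks (S3-Fig-style experiments).
FEATURE_GROUPS <- list(
  AA           = 1:40,
  profile      = 41:60,
  conservation = 61L,
  sec.struct   = 62:70,
  disorder     = 71:73,
  seg          = 74L,
  coiled.coil  = 75L,
  uniprotFeat  = 76:89)

## dbNSFP-style gene-level feature columns used by the +PG extension.
GENE_FEATURE_COLUMNS <- c(
  "ppi_intact", "ppi_biogrid", "ppi_cpdb",
  "ess_crispr1", "ess_crispr2", "ess_trap", "ess_blomen",
  "p_hi", "hipred", "ghis", "gene_indispensability",
  "p_rec", "gdi_phred", "loftool",
  "pli", "prec_lof", "pnull")

aa_index <- function(aa) {
  i <- match(aa, AA_ALPHABET)
  if (anyNA(i)) {
    stop("non-standard amino acid(s): ",
         paste(unique(aa[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}
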