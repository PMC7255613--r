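---
title: "Methods: variant pathogenicity scoring and gene mutation severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant pathogenicity scoring and gene mutation severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The problem

A single-amino-acid variant (SAV) replaces one residue of a human protein.
Most SAVs segregating in the population are benign; a minority disrupt
protein stability or function and cause disease. The package addresses two
questions at two scales:

* **Variant level** — given a substitution and its sequence context, how
  likely is it to be pathogenic? The answer is the *DeepSAV score*, the
  softmax probability of the pathogenic class emitted by a convolutional
  neural network over a 21-residue window of per-position features.
* **Gene level** — how much predicted-deleterious rare variation does a gene
  tolerate in the population? The answer is the *GTS score* (Gene Tolerance
  of rare SAVs): genes under strong purifying selection carry little rare
  damaging variation and score low; tolerant genes score high.

## Positional features and windows

Each protein position is encoded as 90 values, in a fixed documented order
(`deepsav_feature_names()`):

| block | size | content |
|---|---|---|
| wild-type one-hot | 20 | residue identity |
| mutant one-hot | 20 | substituted residue (zero except at the window center) |
| profile | 20 | estimated amino-acid frequencies of the ortholog-alignment column |
| conservation | 1 | normalised-entropy conservation, in [0, 1] |
| secondary structure | 9 | helix/strand/coil calls from three predictors |
| disorder | 3 | disorder propensities from three predictors, in [0, 1] |
| seg, coiled-coil | 2 | low-complexity and coiled-coil flags |
| targeting | 3 | SIGNAL, TRANSIT, TRANSMEM region flags |
| MOD_RES | 3 | phosphorylation, acetylation, methylation site flags |
| other UniProt Features | 8 | DISULFID, CARBOHYD, METAL, BINDING, ACT_SITE, SITE, LIPID, MOTIF |
| padding indicator | 1 | 1 outside the protein's residue range |

The model input is a 21-position window (the variant plus 10 neighbours each
side), flattened to 90 × 21 = 1890 values. Window slots beyond the protein
ends are zero-filled with the padding indicator set to 1; the center is never
padded. Neighbour positions encode their own residue in the wild-type block
with an all-zero mutant block — the substitution itself is visible only at
the center. The structure, disorder and UniProt-style annotations are
consumed as precomputed tables; running the upstream predictors is out of
scope. A gene with no annotation table is imputed as all zeros with a
warning, so a missing file degrades the features rather than failing a run.

Feature-group ablations (`feature_mask()`) zero whole blocks while keeping
the vector length at 90, supporting amino-acid-only, add-one and
leave-one-out experiments; the padding indicator is never masked.

### Profile and conservation

Ortholog alignments are consumed as aligned FASTA (building them is out of
scope). Per reference position, amino-acid frequencies are estimated from
gap- and `X`-excluded counts with a uniform pseudocount (default 0.05 per
residue); Henikoff position-based sequence weighting is available behind a
flag. The literature on profile estimation offers many schemes; this one is
a deliberate, configurable stand-in chosen for transparency. Conservation is
the normalised-entropy score `1 − H/ln 20` of the observed column
frequencies — 1 for invariant columns, 0 for a column uniform over all 20
amino acids — because downstream binning assumes a [0, 1] range. The three
conservation bins are `[0, 0.3)`, `[0.3, 0.6]` and `(0.6, 1]`; the middle
bin owns both printed boundaries so that "larger than 0.6" is honored
literally. The baseline fitness score of a substitution is the profile
log-odds `log2((f_wt + ε)/(f_mut + ε))` with ε = 1e-4 (configurable); it is
antisymmetric under swapping the two residues and serves as a
single-position reference point for the windowed classifier.

## The classifier

The network is a 1-D convolutional architecture over the 21 × 90 window:
seven convolutional layers (200 filters, kernel 3, same-padding), two
max-pooling layers (21 → 10 → 5 positions), and two residual links, followed
by two 100-unit dense layers with dropout 0.5 and a 2-class softmax. Hidden
activations are ReLU. The exact arrangement of the pools and skips within
those totals is under-determined by the counts alone; the package freezes
one canonical layout — conv, then two conv+residual blocks each followed by
a pool, then two more convs — and exposes filters, kernel and dense width in
`deepsav_config()`. The engine is written directly on the BLAS: convolutions
are im2col gathers followed by one matrix product each, and the backward
pass uses the exact transpose operations, verified against finite
differences in the test suite.

Training choices not pinned down by the architecture: Adam (learning rate
1e-3), cross-entropy loss, batch size 128, a maximum of 6 epochs with early
stopping (patience 2) on a stratified 10% validation split. Six epochs
suffices because the planted signal in the synthetic training sets is strong
and the datasets small; all of it is configurable for other regimes. No
class weighting or augmentation is applied: training sets are class-balanced
by construction. Everything stochastic — initialisation, shuffling, dropout,
fold assignment — derives from the configuration seed, so a (seed, data)
pair reproduces a model bit-exactly.

The **+PG** variant concatenates an 18-value side input ahead of the dense
layers: the transformed allele frequency `-log10(MAF + 1e-9)` (raw MAF is
numerically near-degenerate, almost all mass within 1e-4 of zero) and 17
gene-level features (interaction counts, essentiality screens,
haploinsufficiency and loss-of-function constraint scores). Missing values
are imputed with per-column medians; when scoring held-out data, pass the
training-fold medians (`pg_features(..., medians =)`) to avoid leakage.

Evaluation uses the rank-statistic ROC AUC (ties count one half), and
stratified k-fold cross-validation (default k = 4) in which each variant is
validated exactly once and fold AUCs are reported alongside the pooled AUC
over out-of-fold scores.

## Gene-level severity: the GTS score

For one gene,

```
GTS = sum_k DeepSAV_score(k) * MAF(k) / protein_len
```

where the sum runs over the gene's *rare* SAVs (MAF < 1e-4; variants at or
above the cutoff are ignored, making GTS invariant to common variation).
The score is additive over variants and linear in each MAF. Duplicate
records of the same substitution are collapsed to the maximum MAF before
scoring. Genes are then ranked by the inclusive percentile transform
(PERCENTRANK.INC semantics: values strictly below, over n − 1; ties share
their first occurrence) and discretised into deciles by flooring ×10 with
the maximum capped into decile 9. MAF categories follow the printed
boundaries: rare < 1e-4 ≤ low < 1e-3 ≤ medium < 1e-2 ≤ common.

Raw MAFs are used as given; no special treatment of singletons is applied
(the allele-count resolution needed for that is not part of the input
contract).

## Enrichment statistics

The enrichment of a positional property in a variant subset is
`log2(p_subset / p_background)` where each probability is the fraction of
*unique positions* carrying the property (variant events at the same
position count once); the background is the full position table. A property
absent from the subset yields a `-Inf` sentinel, excluded from plots; an
optional 0.5 pseudocount regularises it when requested. Subset-vs-background
swaps negate the score exactly. Disorder propensities are binarised at 0.5
for counting; conservation enters through the three bins.

Disease-class analysis takes a gene-disease association table and reports,
per class, the ratio of its observed frequency among a gene set's
associations to its expected frequency in the whole table; classes below a
configurable minimum association count (default 5) are excluded as sparse.

## Gene-set analyses

The multi-score gene matrix (GTS, LOEUF-like constraint columns, etc.) is
column-Z-scored (sample standard deviation) and then row-centered without
scaling; zero-variance measures are dropped with a warning. Genes are
clustered by complete linkage on correlation distance `1 − r`
(pairwise-complete over missing values; undefined correlations are treated
as maximally distant), with a flat cut into a requested number of clusters —
the number is a parameter here because the "top N clusters" notion of
interactive heatmap tools is tool-internal. Merge ties are resolved by the
underlying `hclust` convention (lowest-index pair first); the test suite
pins the merge sequence to a brute-force all-pairs oracle. Three-way gene
set overlaps return the seven Venn region counts.

## The synthetic-data generator

The generator exists so that every module is testable without downloads. It
emulates the *statistical structure the method assumes*, not human biology:

* **Alignments** — three column classes: invariant (a repeated residue),
  partially conserved (four favoured residues at frequencies
  0.4/0.3/0.2/0.1), and unconstrained (uniform over the 20 amino acids),
  mixed 30/40/30 by default over 120 genes with log-normal lengths (median
  ~400 aa) and 50 sequences. The partially conserved class is what gives the
  profile features something to carry: benign variants preferentially move
  to residues the column already tolerates, pathogenic variants to residues
  the profile excludes. A real alignment's phylogenetic correlation between
  sequences, and its gaps, are *not* emulated.
* **Annotations** — run/block structure for secondary structure, disorder
  segments, low-complexity, coiled-coil and transmembrane tracks; one
  N-terminal targeting peptide at most per gene; point flags (ACT_SITE,
  METAL, ...) as independent Bernoulli tracks. Binary flag base rates
  default to 0.08 — higher than real proteome rates for features like
  ACT_SITE — so that every property keeps an expected count of several
  hundred positions in the ~10^4-position subsets the tests use, i.e. a
  log2-odds standard error of ~0.05 bits. The real study operated at ~10^7
  positions where rare features are still well measured; at desk scale the
  rates, not the statistic, must supply the counts.
* **Planted pathogenicity** — pathogenic positions are sampled with weight
  `exp(1.5 · conservation)` times per-property fold-enrichment weights
  (defaults: 4× at ACT_SITE, DISULFID, METAL, BINDING and SITE; 2× at MOTIF
  and TRANSMEM; 0.5× in disorder calls), times mild wild-type residue odds
  (2× for C and W, 1.5× for G and P) that give the amino-acid-only features
  a signal of their own; benign positions use `exp(−1.5 · conservation)`.
  Property weights are calibrated as `w = o(1−r)/(1−o·r)` against the
  empirical base rate `r`, so a configured fold-change `o` is realised as
  the subset frequency `o·r` in expectation — a 4× planting is recovered as
  a log2 odds of 2.0. Pathogenic substitutions draw the mutant residue with
  probability ∝ `1/(f+0.05)`, benign with ∝ `f+0.02`, where `f` is the
  profile frequency. `neutral_planting()` switches all of this off for null
  simulations.
* **Allele frequencies** — a four-category spectrum (rare/low/medium/common
  = 93.93/4.40/1.10/0.57% by default) with log-uniform MAFs inside each
  band; labeled pathogenic variants draw from an almost-entirely-rare
  spectrum. No population-genetic process (coalescent, selection,
  demography) is simulated — the spectrum is a target, not a consequence.

Because the pathogenic/benign contrast is planted through conservation,
profile compatibility, annotations and residue identity *in that order of
strength*, the feature-ablation experiments have a known qualitative
ordering on synthetic data: amino-acid-only < amino-acid+conservation ≤ all
features. Passing tests therefore demonstrate that the encoder, network and
evaluation recover a signal that is present by construction; they say
nothing about prediction accuracy on real variants, where signal strength,
feature correlations and label noise are very different.

## Numerical choices and degenerate inputs

* Profile pseudocount 0.05 per amino acid; conservation uses raw observed
  frequencies (no pseudocount) so invariant columns score exactly 1.
* Baseline-fitness ε = 1e-4; log base 2 throughout.
* All-gap or all-`X` columns are errors at profile time; a variant whose
  reference residue is `X` is rejected; a wild-type residue that contradicts
  the reference is an error, not a silent correction.
* Zero-variance measures are dropped (with a warning) before Z-scoring;
  genes with fewer than two non-missing measures are excluded from
  clustering.
* `-Inf` enrichment sentinels are excluded from plotting; the optional
  pseudocount is off by default because the headline statistic is a plain
  probability ratio.
* Early stopping keeps the best-validation-loss parameters, not the last
  epoch's.

## Problem sizes

The default test-suite and acceptance problem sizes are chosen as the
smallest at which the statistical claims are stable: 120 genes (~48,000
positions), 4,000+4,000 labeled variants for training-based checks, 10,000
variants for enrichment recovery and 100,000 for spectrum shares. Unit tests
use much smaller configurations (tens of genes, reduced filter counts) since
they check mechanics, not learning capacity.

## Known limitations

* The profile estimator and conservation score are principled stand-ins;
  published pipelines built on specific profile tools will differ in detail.
* The canonical layer arrangement fixes one of several architectures
  consistent with the layer totals; comparisons against externally trained
  weights are out of scope.
* The generator's annotation tracks are independent of conservation by
  design (it keeps planted-enrichment recovery exactly calibrated); real
  functional sites are conserved, so real feature correlations are stronger.
* GTS consumes protein lengths and MAFs as given: isoform choice and
  genomic-to-protein coordinate mapping are the caller's responsibility.
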