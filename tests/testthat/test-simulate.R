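test_that("simulated alignments honor the conservation gradient", {
  ## fully conserved: every column invariant, conservation 1
  a1 <- simulate_alignment(30, n_seqs = 10, conserved_fraction = 1, seed = 9)
  p1 <- estimate_profile(a1)
  expect_equal(p1$conservation, rep(1, 30))
  ## fully variable: low mean conservation at 50 sequences
  a0 <- simulate_alignment(200, n_seqs = 50, conserved_fraction = 0, seed = 9)
  expect_lt(mean(estimate_profile(a0)$conservation), 0.3)
  ## seeded determinism
  expect_identical(simulate_alignment(40, 12, 0.5, seed = 77)$sequences,
                   simulate_alignment(40, 12, 0.5, seed = 77)$sequences)
  ## intermediate columns produce mid-range conservation
  ai <- simulate_alignment(300, 50, 0, seed = 10, intermediate_fraction = 1)
  ci <- estimate_profile(ai)$conservation
  expect_gt(mean(ci), 0.3)
  expect_lt(mean(ci), 0.9)
})

test_that("simulated proteomes are deterministic and well-formed", {
  cfg <- sim_config(n_genes = 5, length_meanlog = log(100),
                    length_sdlog = 0.1, n_seqs = 10)
  p1 <- simulate_proteome(cfg, seed = 12)
  p2 <- simulate_proteome(cfg, seed = 12)
  expect_identical(p1$lengths, p2$lengths)
  expect_identical(p1$genes[[3]]$base, p2$genes[[3]]$base)
  expect_length(p1$genes, 5L)
  for (gd in p1$genes) {
    expect_s3_class(gd, "gene_data")
    expect_equal(nrow(gd$annotations), gd$length)
    expect_true(all(gd$annotations >= 0 & gd$annotations <= 1))
    ## secondary-structure one-hots: each predictor triplet sums to 1
    expect_equal(unname(rowSums(gd$annotations[, 1:3])),
                 rep(1, gd$length))
  }
})

test_that("labeled variant sets match requests and plant the signal", {
  cfg <- sim_config(n_genes = 15, length_meanlog = log(200),
                    length_sdlog = 0.2, n_seqs = 25)
  prot <- simulate_proteome(cfg, seed = 13)
  v <- simulate_labeled_variants(prot, 500, 400, seed = 14)
  expect_equal(sum(v$label == "pathogenic"), 500)
  expect_equal(sum(v$label == "benign"), 400)
  ## no duplicate substitutions, wt matches the reference everywhere
  expect_false(anyDuplicated(paste(v$gene, v$position, v$mut)) > 0)
  for (i in sample(nrow(v), 25)) {
    expect_equal(prot$genes[[v$gene[i]]]$reference[v$position[i]], v$wt[i])
    expect_true(v$mut[i] != v$wt[i])
  }
  ## planted conservation signal: pathogenic sit at more conserved positions
  consv <- mapply(function(g, p) prot$genes[[g]]$profile$conservation[p],
                  v$gene, v$position)
  expect_gt(mean(consv[v$label == "pathogenic"]),
            mean(consv[v$label == "benign"]) + 0.1)
  ## determinism
  v2 <- simulate_labeled_variants(prot, 500, 400, seed = 14)
  expect_identical(v, v2)
  ## impossible requests error out
  tiny_cfg <- sim_config(n_genes = 2, length_meanlog = log(80),
                         length_sdlog = 0.01, n_seqs = 5)
  tiny <- simulate_proteome(tiny_cfg, seed = 1)
  expect_error(simulate_labeled_variants(tiny, 30000, 30000, seed = 1),
               "exceed")
})

test_that("MAF catalogs reproduce the requested spectrum", {
  cfg <- sim_config(n_genes = 10, length_meanlog = log(200),
                    length_sdlog = 0.2, n_seqs = 10)
  prot <- simulate_proteome(cfg, seed = 15)
  cat1 <- simulate_maf_catalog(prot, 20000, seed = 16)
  sp <- summarize_maf_spectrum(cat1)
  w <- prot$config$maf_weights
  expect_equal(sp$percent[sp$category == "rare"] / 100, w[["rare"]],
               tolerance = 0.02)
  expect_true(all(cat1$maf > 0 & cat1$maf <= 1))
  ## weight 1 on common -> all MAF >= 0.01
  cat2 <- simulate_maf_catalog(prot, 500,
                               weights = c(rare = 0, low = 0, medium = 0,
                                           common = 1), seed = 17)
  expect_true(all(cat2$maf >= 0.01))
  ## seeded determinism
  expect_identical(simulate_maf_catalog(prot, 1000, seed = 18),
                   simulate_maf_catalog(prot, 1000, seed = 18))
})

test_that("fixture directories round-trip through the package readers", {
  cfg <- sim_config(n_genes = 4, length_meanlog = log(90),
                    length_sdlog = 0.1, n_seqs = 8)
  prot <- simulate_proteome(cfg, seed = 19)
  vars <- simulate_labeled_variants(prot, 40, 40, seed = 20)
  gf <- simulate_gene_features(names(prot$genes), seed = 21)
  dir <- withr::local_tempdir()
  write_fixture_dir(prot, dir, variants = vars, gene_features = gf)

  ## alignments round-trip bit-exactly
  g <- names(prot$genes)[2]
  aln <- read_alignment(file.path(dir, "alignments", paste0(g, ".fasta")))
  expect_identical(aln$sequences, prot$alignments[[g]]$sequences)
  ## annotations and variants round-trip
  ann <- read_annotations_tsv(file.path(dir, "annotations.tsv"))
  expect_equal(as.matrix(ann[[g]][, deepsav_annotation_columns()]),
               prot$annotations[[g]], ignore_attr = TRUE, tolerance = 1e-12)
  vb <- read_variants_tsv(file.path(dir, "variants.tsv"))
  expect_equal(vb$position, vars$position)
  gl <- read_gene_lengths_tsv(file.path(dir, "gene_lengths.tsv"))
  expect_equal(gl$protein_len, prot$lengths$protein_len)
  gfb <- read_gene_features_tsv(file.path(dir, "gene_features.tsv"))
  expect_equal(gfb$pli, gf$pli, tolerance = 1e-12)
})

test_that("gene feature tables have 17 plausible columns", {
  gf <- simulate_gene_features(paste0("G", 1:50), seed = 22)
  expect_equal(ncol(gf), 18L)  # gene + 17 features
  expect_true(all(gf$pli >= 0 & gf$pli <= 1))
  expect_equal(gf$pli + gf$prec_lof + gf$pnull, rep(1, 50),
               tolerance = 1e-12)
  expect_true(all(gf$ppi_intact >= 0))
})
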