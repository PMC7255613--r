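test_that("profile estimation matches hand-counted frequencies", {
  ## invariant columns, no pseudocount
  aln <- sav_alignment(rep("ACD", 4))
  prof <- estimate_profile(aln, pseudocount = 0)
  expect_equal(dim(prof$freqs), c(3L, 20L))
  expect_equal(unname(prof$freqs[1, "A"]), 1)
  expect_equal(sum(prof$freqs[1, ] > 0), 1L)

  ## 50/50 column by symmetry
  aln2 <- sav_alignment(c("A", "A", "C", "C"))
  prof2 <- estimate_profile(aln2, pseudocount = 0)
  expect_equal(unname(prof2$freqs[1, "A"]), 0.5)
  expect_equal(unname(prof2$freqs[1, "C"]), 0.5)

  ## pseudocount normalisation: (count + 0.05) / (4 + 20*0.05)
  aln3 <- sav_alignment(c("A", "A", "A", "C"))
  prof3 <- estimate_profile(aln3, pseudocount = 0.05)
  expect_equal(unname(prof3$freqs[1, "A"]), 3.05 / 5)
  expect_equal(unname(prof3$freqs[1, "C"]), 1.05 / 5)
  expect_equal(unname(prof3$freqs[1, "D"]), 0.05 / 5)
  expect_equal(sum(prof3$freqs[1, ]), 1, tolerance = 1e-9)
})

test_that("profile rows always sum to one and exclude gaps and X", {
  aln <- sav_alignment(c("ACWDA", "A--DA", "GC-D-", "ACADC"))
  prof <- estimate_profile(aln, pseudocount = 0.05)
  expect_equal(length(prof$positions), 5L)  # ungapped reference
  expect_true(all(abs(rowSums(prof$freqs) - 1) < 1e-9))
  ## column 3 of the alignment has residues W, -, -, A only
  expect_equal(unname(prof$freqs[3, "W"]), 1.05 / 3, tolerance = 1e-9)

  ## gapped reference: positions follow the ungapped reference
  alng <- sav_alignment(c("A-CD", "AWCD", "AWCD"))
  profg <- estimate_profile(alng)
  expect_equal(length(profg$positions), 3L)
  expect_equal(reference_sequence(alng), c("A", "C", "D"))
})

test_that("degenerate inputs are rejected", {
  expect_error(sav_alignment("ACD"), "at least 2")
  expect_error(sav_alignment(c("ACD", "AC")), "same length")
  expect_error(sav_alignment(c("AbZ", "ACD")), "unknown symbols")
  ## reference position whose column holds only gaps and X
  aln <- sav_alignment(c("AX", "A-", "A-", "A-"))
  expect_error(estimate_profile(aln, pseudocount = 0), "no countable|no standard")
})

test_that("conservation score follows normalised entropy", {
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  expect_equal(conservation_score(rep("A", 10)), 1)
  expect_equal(conservation_score(aas), 0)
  ## 50/50 two-residue column: 1 - ln2/ln20
  expect_equal(conservation_score(c("A", "A", "C", "C")),
               1 - log(2) / log(20), tolerance = 1e-12)
  ## monotone: flatter distributions are less conserved
  expect_gt(conservation_score(c("A", "A", "A", "C")),
            conservation_score(c("A", "A", "C", "C")))
  ## invariant to sequence order
  expect_equal(conservation_score(c("C", "A", "C", "A")),
               conservation_score(c("A", "A", "C", "C")))
  expect_error(conservation_score(c("-", "-")), "no standard")
})

test_that("duplicating a sequence leaves an invariant column unchanged", {
  ## with no pseudocount the relative frequencies depend only on the
  ## composition, so a duplicated sequence changes nothing
  aln <- sav_alignment(c("AAA", "AAA", "AAA"))
  aln2 <- sav_alignment(c("AAA", "AAA", "AAA", "AAA"))
  expect_equal(estimate_profile(aln, pseudocount = 0)$freqs,
               estimate_profile(aln2, pseudocount = 0)$freqs)
  expect_equal(estimate_profile(aln)$conservation,
               estimate_profile(aln2)$conservation)
})

test_that("conservation bins honor the 0.3 / 0.6 boundaries", {
  expect_equal(bin_conservation(0.2), "Consv1")
  expect_equal(bin_conservation(0.45), "Consv2")
  expect_equal(bin_conservation(0.7), "Consv3")
  expect_equal(bin_conservation(c(0, 0.3, 0.6, 1)),
               c("Consv1", "Consv2", "Consv2", "Consv3"))
  expect_error(bin_conservation(1.2), "0, 1")
})

test_that("baseline fitness is a log2 profile odds, antisymmetric", {
  f <- numeric(20); names(f) <- deepsav_feature_names()[41:60]
  f <- rep(0.05, 20); names(f) <- c("A","C","D","E","F","G","H","I","K","L",
                                    "M","N","P","Q","R","S","T","V","W","Y")
  expect_equal(baseline_fitness(f, "A", "C"), 0)
  f2 <- f; f2["A"] <- 0.8; f2["C"] <- 0.2
  expect_equal(baseline_fitness(f2, "A", "C", epsilon = 0), 2)
  ## antisymmetry for arbitrary columns
  set.seed(1)
  for (i in 1:20) {
    fr <- stats::runif(20); fr <- fr / sum(fr)
    names(fr) <- names(f)
    pair <- sample(names(f), 2)
    expect_equal(baseline_fitness(fr, pair[1], pair[2]),
                 -baseline_fitness(fr, pair[2], pair[1]))
  }
  expect_error(baseline_fitness(f, "A", "A"), "differ")
})

test_that("alignment FASTA round-trips through read/write", {
  aln <- tiny_alignment()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path)
  expect_equal(back$sequences, aln$sequences)
  expect_equal(estimate_profile(back)$freqs, estimate_profile(aln)$freqs)
})

test_that("profile TSV round-trips", {
  prof <- estimate_profile(tiny_alignment())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, "G1", path)
  back <- read_profile_tsv(path)
  expect_equal(nrow(back), 6L)
  expect_equal(as.numeric(back$conservation), prof$conservation)
  expect_equal(as.matrix(back[, LETTERS[c(1, 3, 4)]]),
               prof$freqs[, c("A", "C", "D")], ignore_attr = TRUE)
})
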