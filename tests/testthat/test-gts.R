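test_that("MAF categories partition (0,1] with printed boundaries", {
  expect_equal(maf_category(0.05), "common")
  expect_equal(maf_category(0.00005), "rare")
  expect_equal(maf_category(0.0001), "low")
  expect_equal(maf_category(0.001), "medium")
  expect_equal(maf_category(0.01), "common")
  expect_equal(maf_category(1), "common")
  ## every MAF maps to exactly one label
  set.seed(1)
  m <- exp(runif(500, log(1e-7), log(1)))
  expect_false(anyNA(maf_category(m)))
  expect_error(maf_category(0), "\\(0, 1\\]")
  expect_error(maf_category(1.5), "\\(0, 1\\]")
})

test_that("MAF spectrum summaries recover catalog shares", {
  ## worked shares from per-category counts
  counts <- c(rare = 4588805, low = 215132, medium = 53489, common = 27813)
  sp <- summarize_maf_spectrum(counts)
  expect_equal(sum(sp$count), 4885239)
  expect_equal(sp$percent[sp$category == "common"], 100 * 27813 / 4885239)
  expect_equal(round(sp$percent[sp$category == "common"], 2), 0.57)
  expect_equal(round(sp$percent[sp$category == "rare"]), 94)
  expect_equal(sum(sp$percent), 100)
  ## from a raw MAF vector
  sp2 <- summarize_maf_spectrum(c(0.5, 0.00005, 0.00005, 0.005))
  expect_equal(sp2$count, c(2, 0, 1, 1))
  ## single-variant catalog: one category at 100%
  sp3 <- summarize_maf_spectrum(data.frame(maf = 0.2))
  expect_equal(sp3$percent[sp3$category == "common"], 100)
})

test_that("GTS equals the length-normalised rare MAF-weighted score sum", {
  ## no rare SAVs -> 0
  expect_equal(gts_score(c(0.9, 0.5), c(0.01, 0.2), 100), 0)
  ## direct substitution
  expect_equal(gts_score(0.8, 5e-5, 100), 0.8 * 5e-5 / 100)
  expect_equal(gts_score(0.8, 5e-5, 100), 4e-7)
  ## brute-force oracle on three rare SAVs
  s <- c(0.8, 0.3, 0.99); m <- c(5e-5, 1e-5, 9.9e-5)
  expect_equal(gts_score(s, m, 7), sum(s * m) / 7, tolerance = 1e-15)
  ## SAVs at the cutoff are ignored (strict <)
  expect_equal(gts_score(c(0.5, 0.5), c(1e-4, 5e-5), 10),
               0.5 * 5e-5 / 10)
  expect_error(gts_score(0.5, 1e-5, 0), ">= 1")
})

test_that("GTS is additive, monotone under SAV removal, and MAF-linear", {
  set.seed(2)
  s <- runif(20); m <- exp(runif(20, log(1e-6), log(9e-5)))
  full <- gts_score(s, m, 50)
  expect_equal(full, sum(vapply(1:20, function(i)
    gts_score(s[i], m[i], 50), numeric(1))))
  for (i in sample(20, 5)) {
    expect_lte(gts_score(s[-i], m[-i], 50), full)
  }
  expect_equal(gts_score(s, m / 2, 50), full / 2)
  ## invariant to adding non-rare SAVs
  expect_equal(gts_score(c(s, 1, 1), c(m, 0.01, 0.5), 50), full)
})

test_that("deleterious counts use a strict threshold and the rare filter", {
  expect_equal(count_deleterious(c(0.75, 0.76), c(1e-5, 1e-5)), 1)
  expect_equal(count_deleterious(numeric(0), numeric(0)), 0)
  expect_equal(count_deleterious(0.9, 0.5, rare_only = TRUE), 0)
  expect_equal(count_deleterious(0.9, 0.5, rare_only = FALSE), 1)
})

test_that("percentile ranks follow the inclusive percentrank convention", {
  x <- c(3, 1, 2)
  expect_equal(percent_rank(x), c(1, 0, 0.5))
  expect_equal(percentile_decile(c(0, 0.09, 0.1, 0.95, 1)),
               c(0L, 0L, 1L, 9L, 9L))
  ## ties share the percentile of their first occurrence: sort-and-scan oracle
  set.seed(3)
  for (rep in 1:10) {
    x <- sample(round(runif(30), 1))  # duplicates likely
    p <- percent_rank(x)
    oracle <- vapply(x, function(v) sum(x < v) / (length(x) - 1), numeric(1))
    expect_equal(p, oracle)
  }
  expect_error(percent_rank(5), "at least 2")
})

test_that("gene tolerance tables aggregate, rank and sort correctly", {
  lengths <- data.frame(gene = c("A", "B", "C", "D"),
                        protein_len = c(100, 200, 50, 400))
  v <- data.frame(
    gene = c("A", "A", "B", "C", "C", "C"),
    position = c(1, 2, 5, 1, 2, 3),
    wt = "A", mut = c("C", "D", "C", "C", "D", "E"),
    maf = c(5e-5, 2e-5, 1e-5, 5e-2, 9e-5, 9e-5),
    deepsav_score = c(0.9, 0.8, 0.1, 0.99, 0.8, 0.2))
  tol <- gene_tolerance_table(v, lengths)
  expect_equal(nrow(tol), 4L)
  expect_equal(tol$gts[tol$gene == "D"], 0)       # no variants
  expect_equal(tol$gts[tol$gene == "A"],
               (0.9 * 5e-5 + 0.8 * 2e-5) / 100)
  expect_equal(tol$gts, sort(tol$gts))            # ascending output
  ## decile/percentile endpoints
  expect_equal(tol$percentile[which.min(tol$gts)], 0)
  expect_equal(tol$decile[which.min(tol$gts)], 0L)
  expect_equal(tol$percentile[which.max(tol$gts)], 1)
  expect_equal(tol$decile[which.max(tol$gts)], 9L)
  ## deleterious counts: rare + score > 0.75
  expect_equal(tol$n_deleterious[tol$gene == "A"], 2L)
  expect_equal(tol$n_deleterious[tol$gene == "C"], 1L)
  expect_equal(tol$n_rare_savs[tol$gene == "C"], 2L)

  ## duplicate records collapse to maximum MAF
  v2 <- rbind(v, data.frame(gene = "A", position = 1, wt = "A", mut = "C",
                            maf = 9e-5, deepsav_score = 0.9))
  expect_message(tol2 <- gene_tolerance_table(v2, lengths), "duplicate")
  expect_equal(tol2$gts[tol2$gene == "A"], (0.9 * 9e-5 + 0.8 * 2e-5) / 100)
  expect_error(gene_tolerance_table(v, lengths[1, , drop = FALSE]),
               "at least 2 genes")
})

test_that("decile histogram over all genes is near-uniform by construction", {
  set.seed(4)
  n <- 173
  gts <- runif(n)
  dec <- percentile_decile(percent_rank(gts))
  counts <- table(factor(dec, levels = 0:9))
  expect_true(all(abs(counts - n / 10) <= 1))
})
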