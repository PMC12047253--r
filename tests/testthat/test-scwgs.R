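p1 <- default_beta_params("primary")
th <- calling_thresholds()

mk_cc <- function(sites) {
  # sites: list of list(pos, an_alt, an_depth, di_alt, di_depth)
  rows <- lapply(sites, function(s) {
    data.table::data.table(
      chrom = "chr1", pos = s$pos, ref = "A",
      pool = c("aneuploid", "diploid"),
      A = c(s$an_depth - s$an_alt, s$di_depth - s$di_alt),
      C = 0L, G = c(s$an_alt, s$di_alt), T = 0L, other = 0L)
  })
  clone_counts(data.table::rbindlist(rows))
}

test_that("scWGS support labels follow eligibility and per-pool significance", {
  cc <- mk_cc(list(
    list(pos = 100L, an_alt = 20L, an_depth = 40L, di_alt = 0L, di_depth = 40L),
    list(pos = 200L, an_alt = 20L, an_depth = 40L, di_alt = 20L, di_depth = 40L),
    list(pos = 300L, an_alt = 0L, an_depth = 40L, di_alt = 0L, di_depth = 40L),
    list(pos = 400L, an_alt = 0L, an_depth = 8L, di_alt = 0L, di_depth = 8L),
    list(pos = 500L, an_alt = 1L, an_depth = 3L, di_alt = 0L, di_depth = 2L)))
  loci <- data.table::data.table(chrom = "chr1",
                                 pos = c(100L, 200L, 300L, 400L, 500L),
                                 ref = "A", alt = "G")
  got <- classify_support(loci, cc, p1, th)
  expect_identical(got$label,
                   c("somatic",     # significant in aneuploid pool only
                     "germline",    # significant in the diploid pool
                     "uncalled",    # significant in neither
                     "ineligible",  # 0 mutated reads, 16 < 17 coverage
                     "somatic"))    # eligible via >= 1 mutated read
  # the 17-read boundary makes the mutation-free locus eligible
  cc17 <- mk_cc(list(list(pos = 400L, an_alt = 0L, an_depth = 9L,
                          di_alt = 0L, di_depth = 8L)))
  got17 <- classify_support(loci[4L], cc17, p1, th)
  expect_identical(got17$label, "uncalled")
})

test_that("the de novo truth set applies the dual-threshold rule", {
  cc <- mk_cc(list(
    list(pos = 100L, an_alt = 20L, an_depth = 40L, di_alt = 0L, di_depth = 40L),
    list(pos = 200L, an_alt = 20L, an_depth = 40L, di_alt = 20L, di_depth = 40L),
    list(pos = 300L, an_alt = 20L, an_depth = 40L, di_alt = 0L, di_depth = 40L)))
  mk_rna <- function(depths) {
    tab <- base_count_table(
      data.table::data.table(chrom = "chr1", pos = c(100L, 200L, 300L),
                             ref = "A", barcode = "B1", A = depths, C = 0L,
                             G = 0L, T = 0L, other = 0L),
      c(B1 = "cancer"))
    aggregate_pseudobulk(tab, "B1", "x")
  }
  rna <- mk_rna(c(10L, 10L, 4L))  # the third site lacks scRNA coverage
  cells <- data.table::data.table(chrom = "chr1", pos = c(100L, 100L),
                                  cell = c("W1", "W2"),
                                  alt_reads = c(5L, 3L))
  got <- call_scwgs_denovo(cc, rna, rna, p1, cell_alt_counts = cells, th)
  # site 100: aneuploid p < 0.001, diploid p > 0.05, >= 3 alt reads in
  # two cells -> somatic truth
  expect_identical(got$pos, 100L)
  expect_true(got$somatic)
  expect_lt(got$p_aneuploid, 0.001)
  expect_gt(got$p_diploid, 0.05)
  # without per-cell counts the sub-filter is skipped with a message
  expect_message(
    got2 <- call_scwgs_denovo(cc, rna, rna, p1, cell_alt_counts = NULL, th),
    "skipping")
  expect_setequal(got2$pos, c(100L, 200L))
  # the germline-like site fails the diploid p > 0.05 requirement
  expect_false(got2[got2$pos == 200L]$somatic)
})

test_that("performance statistics follow the documented conventions", {
  mk <- function(pos) data.table::data.table(chrom = "chr1", pos = pos)
  perf <- performance(mk(1:10), mk(6:15))
  expect_equal(perf$tp, 5L); expect_equal(perf$fp, 5L); expect_equal(perf$fn, 5L)
  expect_equal(perf$precision, 0.5)
  expect_equal(perf$sensitivity, 0.5)
  expect_equal(perf$f1, 0.5)
  perfect <- performance(mk(1:5), mk(1:5))
  expect_equal(perfect$precision, 1); expect_equal(perfect$f1, 1)
  none <- performance(mk(integer(0)), mk(1:5))
  expect_true(none$no_calls)
  expect_equal(none$precision, 0)
  expect_equal(none$sensitivity, 0)
  # F1 is the harmonic mean whenever P + R > 0
  set.seed(3)
  for (i in 1:20) {
    a <- mk(sample(1:50, 20L)); b <- mk(sample(1:50, 20L))
    p <- performance(a, b)
    if (p$precision + p$sensitivity > 0)
      expect_equal(p$f1, 2 * p$precision * p$sensitivity /
                     (p$precision + p$sensitivity), tolerance = 1e-12)
  }
  # the eligibility universe restricts both calls and truth
  perf_el <- performance(mk(1:10), mk(6:15), eligible = mk(6:10))
  expect_equal(perf_el$tp, 5L)
  expect_equal(perf_el$fp, 0L)
  expect_equal(perf_el$fn, 0L)
})

test_that("paired synthetic scRNA + scWGS data classifies planted loci", {
  sim <- cached_sim(13)
  truth <- sim$truth$sites
  loci <- truth[truth$class %in% c("somatic", "germline", "mt_somatic"),
                c("chrom", "pos", "ref", "alt", "class"), with = FALSE]
  got <- classify_support(loci[, c("chrom", "pos", "ref", "alt"),
                               with = FALSE], sim$clone_counts, p1, th)
  got <- merge(got, loci, by = c("chrom", "pos", "ref", "alt"))
  som <- got[got$class %in% c("somatic", "mt_somatic") &
               got$label != "ineligible"]
  germ <- got[got$class == "germline" & got$label != "ineligible"]
  expect_gte(mean(som$label == "somatic"), 0.95)
  expect_gte(mean(germ$label == "germline"), 0.95)
})
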