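p1 <- default_beta_params("primary")
p2 <- default_beta_params("other")
th <- calling_thresholds()

mk_pb <- function(A, C, G, T, ref = "A", pos = 1000L) {
  dt <- data.table::data.table(chrom = "chr1", pos = pos, ref = ref,
                               A = A, C = C, G = G, T = T, other = 0L)
  dt[, depth := A + C + G + T + other]
  dt
}

test_that("candidate detection applies depth/alt thresholds and the tie-break", {
  # depth 5 with one mutated read: candidate
  expect_equal(nrow(detect_candidates(mk_pb(4L, 1L, 0L, 0L))), 1L)
  # depth 4 with two mutated reads: below the coverage floor
  expect_equal(nrow(detect_candidates(mk_pb(2L, 2L, 0L, 0L))), 0L)
  # tie between C and G resolves to C (base order A < C < G < T)
  cand <- detect_candidates(mk_pb(4L, 3L, 3L, 0L))
  expect_equal(cand$alt, "C")
  expect_equal(cand$cancer_alt, 3L)
  expect_equal(cand$cancer_nonref, 6L)
  # loci with zero non-reference reads never become candidates
  expect_equal(nrow(detect_candidates(mk_pb(50L, 0L, 0L, 0L))), 0L)
})

test_that("coverage and alt-support filters use inclusive count thresholds", {
  expect_false(filter_coverage(make_records(cancer_depth = 10L,
                                            noncancer_depth = 4L), th))
  expect_true(filter_coverage(make_records(cancer_depth = 5L,
                                           noncancer_depth = 5L), th))
  expect_false(filter_coverage(make_records(cancer_depth = 0L), th))
  expect_true(filter_alt_support(make_records(n_cancer_cells_alt3 = 2L), th))
  expect_false(filter_alt_support(make_records(n_cancer_cells_alt3 = 1L), th))
  expect_false(filter_alt_support(make_records(n_cancer_cells_alt3 = 0L), th))
})

test_that("per-cell alt support is counted from the table", {
  # cells with alt reads {3, 3} support the locus; {5, 2} has only one
  # qualifying cell; an absent locus has none
  mk_tab <- function(alts) {
    base_count_table(
      data.table::data.table(
        chrom = "chr1", pos = 1000L, ref = "A",
        barcode = sprintf("BC%d", seq_along(alts)),
        A = 10L, C = as.integer(alts), G = 0L, T = 0L, other = 0L),
      stats::setNames(c(rep("cancer", length(alts)), "noncancer"),
                      sprintf("BC%d", seq_len(length(alts) + 1L))))
  }
  r33 <- build_variant_records(mk_tab(c(3L, 3L)), params = p1, thresholds = th)
  expect_equal(r33$n_cancer_cells_alt3, 2L)
  expect_true(filter_alt_support(r33, th))
  r52 <- build_variant_records(mk_tab(c(5L, 2L)), params = p1, thresholds = th)
  expect_equal(r52$n_cancer_cells_alt3, 1L)
  expect_false(filter_alt_support(r52, th))
})

test_that("noise and other-allele tests agree with the oracle tails", {
  # zero alternative reads: p = 1, filtered as noise
  expect_false(filter_noise_cancer(make_records(cancer_alt = 0L), p1, th))
  # 10 alt of depth 20: the oracle tail is far below 0.001
  expect_lt(oracle_bb_tail(10, 20, 0.21, 104.95), 1e-3)
  expect_true(filter_noise_cancer(
    make_records(cancer_alt = 10L, cancer_depth = 20L), p1, th))
  # residual non-reference alleles: only ref + alt present passes
  expect_true(filter_other_allele_noise(
    make_records(cancer_nonref = 20L, cancer_alt = 20L), p2, th))
  # 5 residual non-reference reads among 20 residual: oracle flags it
  expect_lt(oracle_bb_tail(5, 20, 0.25, 162.04), 0.05)
  expect_false(filter_other_allele_noise(
    make_records(cancer_alt = 20L, cancer_depth = 40L,
                 cancer_nonref = 25L), p2, th))
  # depth equal to alt (n' = 0) is vacuously clean
  expect_true(filter_other_allele_noise(
    make_records(cancer_alt = 40L, cancer_depth = 40L,
                 cancer_nonref = 40L), p2, th))
})

test_that("homopolymer proximity uses tract plus flank", {
  res <- annotation_resources(
    homopolymers = data.table::data.table(chrom = "chr1", start = 100L,
                                          end = 108L, base = "A"))
  probe <- function(pos) filter_homopolymer(make_records(pos = pos), res, th)
  expect_false(probe(103L))  # inside the tract
  expect_false(probe(96L))   # 4 bp before the start
  expect_false(probe(111L))  # 4 bp past the last base (107)
  expect_true(probe(95L))    # 5 bp before
  expect_true(probe(112L))   # 5 bp past
  expect_true(filter_homopolymer(make_records(chrom = "chr9"), res, th))
})

test_that("site-list and frequency filters match on locus (and allele)", {
  res <- annotation_resources(
    editing = data.table::data.table(chrom = "chr1", pos = 100000L),
    pon_sr = data.table::data.table(chrom = "chr1", pos = 150000L),
    pon_lr = data.table::data.table(chrom = "chr1", pos = c(150000L, 200000L)),
    gnomad = data.table::data.table(chrom = "chr1",
                                    pos = c(250000L, 300000L),
                                    alt = "G", af = c(0.01, 0.009)))
  rec <- make_records(5L, pos = c(100000L, 150000L, 200000L, 250000L, 300000L))
  expect_identical(filter_editing(rec, res), c(FALSE, TRUE, TRUE, TRUE, TRUE))
  # either panel fails the locus; LR-only membership also fails
  expect_identical(filter_pon(rec, res, "both"),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(filter_pon(rec, res, "lr"),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE))
  # AF exactly 1% fails ("at least 1%"); 0.9% passes; absent passes
  expect_identical(filter_gnomad(rec, res, th),
                   c(TRUE, TRUE, TRUE, FALSE, TRUE))
  # a different allele at a listed position is not the listed variant
  rec_t <- make_records(1L, pos = 250000L, alt = "T")
  expect_true(filter_gnomad(rec_t, res, th))
})

test_that("the germline test is strict and flags heterozygous profiles", {
  expect_true(filter_germline(make_records(noncancer_alt = 0L,
                                           noncancer_depth = 20L), p1, th))
  expect_lt(oracle_bb_tail(8, 16, 0.21, 104.95), 0.05)
  expect_false(filter_germline(make_records(noncancer_alt = 8L,
                                            noncancer_depth = 16L), p1, th))
  # p exactly at the level passes (strict <): uniform prior tail(2,4) = 0.6
  u <- beta_params(1, 1)
  th6 <- calling_thresholds(germline_level = 0.6)
  expect_true(filter_germline(make_records(noncancer_alt = 2L,
                                           noncancer_depth = 4L), u, th6))
})

test_that("simulated heterozygous sites are rejected with probability >= 0.99", {
  set.seed(77)
  n <- sample(20:60, 500L, replace = TRUE)
  k <- rbinom(500L, n, 0.5)
  rec <- make_records(500L, pos = seq(1e5, by = 5e4, length.out = 500L),
                      noncancer_alt = k, noncancer_depth = n)
  expect_gte(mean(!filter_germline(rec, p1, th)), 0.99)
})

test_that("distance filtering removes both members of close pairs", {
  rec <- make_records(2L, pos = c(1000L, 9000L))
  expect_identical(filter_distance(rec, th), c(FALSE, FALSE))
  rec <- make_records(2L, pos = c(9000L, 25000L))  # 16 kb apart
  expect_identical(filter_distance(rec, th), c(TRUE, TRUE))
  expect_identical(filter_distance(make_records(1L), th), TRUE)
  # loci on different chromosomes are never neighbours
  rec <- make_records(2L, chrom = c("chr1", "chr2"), pos = c(1000L, 2000L))
  expect_identical(filter_distance(rec, th), c(TRUE, TRUE))
})

test_that("distance filtering equals the brute-force pairwise oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:200, 1L)
    chrom <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
    pos <- sample(1:300000, n)
    rec <- make_records(n, chrom = chrom, pos = pos)
    expect_identical(filter_distance(rec, th),
                     oracle_distance_keep(chrom, pos, th$min_distance))
  }
})

test_that("filters 1-9 commute: any order yields the same survivors", {
  sim <- cached_sim(19)
  rec <- build_variant_records(sim$table, sim$cell_types, p1, th)
  rec <- rec[!chrom %in% th$mt_chroms]
  fns <- list(
    function(r) filter_coverage(r, th),
    function(r) filter_alt_support(r, th),
    function(r) filter_noise_cancer(r, p1, th),
    function(r) filter_other_allele_noise(r, p2, th),
    function(r) filter_homopolymer(r, sim$resources, th),
    function(r) filter_editing(r, sim$resources),
    function(r) filter_pon(r, sim$resources, "both"),
    function(r) filter_germline(r, p1, th),
    function(r) filter_gnomad(r, sim$resources, th))
  ref_surv <- Reduce(`&`, lapply(fns, function(f) f(rec)))
  for (s in 1:3) {
    set.seed(s)
    perm <- sample(fns)
    expect_identical(Reduce(`&`, lapply(perm, function(f) f(rec))), ref_surv)
  }
})

test_that("the full battery separates planted classes with a conserved funnel", {
  sim <- cached_sim(19)
  res <- quiet_pipeline(sim$table, sim$cell_types, sim$resources,
                        sim$fusion_calls)
  cs <- res$snv
  # funnel conservation at every step
  expect_equal(cs$funnel$n_pass, cs$funnel$n_in - cs$funnel$n_fail)
  expect_equal(cs$funnel$n_in[-1L], cs$funnel$n_pass[-nrow(cs$funnel)])
  expect_equal(cs$funnel$n_in[1L], nrow(cs$records))
  # every candidate has a complete ledger over the per-record steps
  for (step in c("coverage", "alt_support", "noise_cancer", "other_noise",
                 "homopolymer", "editing", "pon", "germline", "gnomad"))
    expect_false(anyNA(cs$records[[paste0("pass_", step)]]))
  # planted germline sites all fail the germline or population filter
  truth <- sim$truth$sites
  germ <- truth[truth$class == "germline"]
  g <- cs$records[paste(chrom, pos) %in% paste(germ$chrom, germ$pos)]
  expect_true(all(!g$pass_germline | !g$pass_gnomad))
  expect_equal(length(intersect(paste(cs$somatic$chrom, cs$somatic$pos),
                                paste(germ$chrom, germ$pos))), 0L)
  # planted somatic sites are recovered
  som <- truth[truth$class == "somatic"]
  hit <- intersect(paste(cs$somatic$chrom, cs$somatic$pos),
                   paste(som$chrom, som$pos))
  expect_gte(length(hit) / nrow(som), 0.9)
})

test_that("close somatic pairs are removed even when truly somatic", {
  rec <- make_records(3L, pos = c(100000L, 105000L, 400000L))
  cs <- call_somatic_snvs(records = rec, resources = annotation_resources(),
                          params1 = p1, params2 = p2, thresholds = th)
  # the pair 5 kb apart is dropped by the final step, the lone one kept
  expect_equal(cs$somatic$pos, 400000L)
  expect_identical(cs$records$pass_distance, c(FALSE, FALSE, TRUE))
})

test_that("an empty candidate set yields an empty call set with a zero funnel", {
  cs <- call_somatic_snvs(records = make_records(0L),
                          resources = annotation_resources(),
                          params1 = p1, params2 = p2, thresholds = th)
  expect_equal(nrow(cs$somatic), 0L)
  expect_true(all(cs$funnel$n_in == 0L))
})

test_that("VCF output carries PASS or the first failing step", {
  rec <- make_records(3L, pos = c(100000L, 200000L, 300000L))
  rec$noncancer_depth[2L] <- 3L  # fails coverage
  rec$noncancer_alt[3L] <- 20L   # fails germline
  rec$vaf_noncancer <- rec$noncancer_alt / rec$noncancer_depth
  cs <- call_somatic_snvs(records = rec, resources = annotation_resources(),
                          params1 = p1, params2 = p2, thresholds = th)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_call_vcf(cs, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  filt <- vapply(strsplit(body, "\t"), `[[`, character(1L), 7L)
  expect_identical(filt, c("PASS", "coverage", "germline"))
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_funnel(cs$funnel, fpath)
  back <- data.table::fread(fpath)
  expect_equal(back$n_pass, cs$funnel$n_pass)
})
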