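p1 <- default_beta_params("primary")
p2 <- default_beta_params("other")
th <- calling_thresholds()
empty_res <- annotation_resources()

test_that("HCCV selection enforces the stringent coverage and enrichment rules", {
  # 19 reads in noncancer fails the 20-read floor
  r <- make_records(cancer_depth = 40L, noncancer_depth = 19L)
  expect_equal(nrow(select_hccv_snvs(r, empty_res, p2, th)$somatic), 0L)
  r20 <- make_records(cancer_depth = 20L, noncancer_depth = 20L)
  expect_equal(nrow(select_hccv_snvs(r20, empty_res, p2, th)$somatic), 1L)
  # VAF_noncancer 0.25 is rejected; 0.15 with delta MCF 0.5 is kept
  r <- make_records(noncancer_alt = 10L, noncancer_depth = 40L)  # VAF 0.25
  expect_equal(nrow(select_hccv_snvs(r, empty_res, p2, th)$somatic), 0L)
  r <- make_records(noncancer_alt = 6L, noncancer_depth = 40L,   # VAF 0.15
                    mcf_cancer = 0.55, mcf_noncancer = 0.05)     # dMCF 0.5
  expect_equal(nrow(select_hccv_snvs(r, empty_res, p2, th)$somatic), 1L)
  # delta MCF exactly 0.4 is rejected (strict >)
  r <- make_records(mcf_cancer = 0.45, mcf_noncancer = 0.05)
  expect_equal(r$delta_mcf, 0.4)
  expect_equal(nrow(select_hccv_snvs(r, empty_res, p2, th)$somatic), 0L)
  r <- make_records(mcf_cancer = 0.46, mcf_noncancer = 0.05)
  expect_equal(nrow(select_hccv_snvs(r, empty_res, p2, th)$somatic), 1L)
})

test_that("HCCV selection applies the close-pair rule to survivors", {
  r <- make_records(3L, pos = c(100000L, 105000L, 400000L))
  got <- select_hccv_snvs(r, empty_res, p2, th)
  expect_equal(got$somatic$pos, 400000L)
})

test_that("mitochondrial HCCVs use only the LR panel and skip the distance rule", {
  res <- annotation_resources(
    pon_sr = data.table::data.table(chrom = "chrM", pos = 3000L),
    pon_lr = data.table::data.table(chrom = "chrM", pos = 5000L))
  # SR-panel membership does not disqualify a mitochondrial locus
  r <- make_records(chrom = "chrM", pos = 3000L)
  expect_equal(nrow(select_hccv_mtsnvs(r, res, p2, th)$somatic), 1L)
  # LR-panel membership does
  r <- make_records(chrom = "chrM", pos = 5000L)
  expect_equal(nrow(select_hccv_mtsnvs(r, res, p2, th)$somatic), 0L)
  # two close mitochondrial loci both survive (no distance rule on chrM)
  r <- make_records(2L, chrom = "chrM", pos = c(2000L, 2500L))
  expect_equal(nrow(select_hccv_mtsnvs(r, res, p2, th)$somatic), 2L)
  # the enrichment rule still applies
  r <- make_records(chrom = "chrM", pos = 2000L, mcf_cancer = 0.3)
  expect_equal(nrow(select_hccv_mtsnvs(r, res, p2, th)$somatic), 0L)
})

test_that("fusion HCCV thresholds are strict at both boundaries", {
  ct <- stats::setNames(rep(c("cancer", "noncancer"), c(100L, 200L)),
                        sprintf("BC%03d", 1:300))
  mk_calls <- function(n_c, n_n) data.table::data.table(
    fusion_name = "AA--BB",
    barcode = c(sprintf("BC%03d", seq_len(n_c)),
                sprintf("BC%03d", 100L + seq_len(n_n))))
  expect_equal(nrow(select_hccv_fusions(mk_calls(6L, 0L), ct, th)), 1L)
  expect_equal(nrow(select_hccv_fusions(mk_calls(5L, 0L), ct, th)), 0L)   # 5% exactly
  expect_equal(nrow(select_hccv_fusions(mk_calls(10L, 2L), ct, th)), 0L)  # 1% exactly
})

test_that("cells reannotate by the covered-HCCV mutation fraction", {
  # ten HCCV loci; three cells with controlled coverage/mutation profiles
  loci <- data.table::data.table(chrom = "chr1",
                                 pos = seq(100000L, by = 50000L,
                                           length.out = 10L),
                                 ref = "A", alt = "G")
  rows <- list(
    # cell X covers 4 loci, clearly mutated at exactly one: 25% -> cancer
    data.table::data.table(chrom = "chr1", pos = loci$pos[1:4], ref = "A",
                           barcode = "X", A = c(0L, 10L, 10L, 10L),
                           C = 0L, G = c(10L, 0L, 0L, 0L), T = 0L, other = 0L),
    # cell Y covers only 2 loci: filtered
    data.table::data.table(chrom = "chr1", pos = loci$pos[1:2], ref = "A",
                           barcode = "Y", A = 10L, C = 0L, G = 0L, T = 0L,
                           other = 0L),
    # cell Z covers all 10, none mutated: noncancer
    data.table::data.table(chrom = "chr1", pos = loci$pos, ref = "A",
                           barcode = "Z", A = 10L, C = 0L, G = 0L, T = 0L,
                           other = 0L))
  tab <- base_count_table(data.table::rbindlist(rows),
                          c(X = "noncancer", Y = "cancer", Z = "noncancer"))
  re <- reannotate_cells(tab, hccv_snvs = loci, params1 = p1, thresholds = th)
  expect_equal(re[re$barcode == "X"]$fraction, 0.25)
  expect_equal(re[re$barcode == "X"]$new_label, "cancer")   # >= 25% inclusive
  expect_equal(re[re$barcode == "Y"]$new_label, "filtered") # < 3 covered
  expect_equal(re[re$barcode == "Z"]$new_label, "noncancer")
  sm <- reannotation_summary(re)
  expect_equal(sum(sm$n), 3L)
})

test_that("mislabelled cancer cells are recovered and noncancer cells stay", {
  sim <- cached_sim(13)
  res <- quiet_pipeline(sim$table, sim$cell_types, sim$resources,
                        sim$fusion_calls)
  truth <- sim$truth$cells
  lab <- res$labels
  mis <- truth[truth$mislabeled == TRUE]
  expect_gte(mean(lab[mis$barcode] == "cancer"), 0.95)
  nonc <- truth[truth$true_label == "noncancer"]
  flipped <- mean(lab[nonc$barcode] == "cancer")
  expect_lte(flipped, 0.01)
})

test_that("reannotation is idempotent on synthetic data", {
  sim <- cached_sim(13)
  res1 <- quiet_pipeline(sim$table, sim$cell_types, sim$resources,
                         sim$fusion_calls)
  # feed the reannotated labels back through the selection+reannotation pass
  tab2 <- base_count_table(data.table::as.data.table(sim$table),
                           res1$labels[res1$labels != "filtered"],
                           droplets = attr(sim$table, "droplets"))
  res2 <- quiet_pipeline(tab2, cell_labels(tab2), sim$resources,
                         sim$fusion_calls)
  common <- intersect(names(res1$labels), names(res2$labels))
  changed <- mean(res1$labels[common] != res2$labels[common])
  expect_lt(changed, 0.01)
})
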