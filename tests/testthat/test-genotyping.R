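p1 <- default_beta_params("primary")

test_that("nuclear genotypes follow the alt-vs-ref beta-binomial rule", {
  expect_identical(genotype_cell_snv(0L, 0L, p1), "missing")
  expect_identical(genotype_cell_snv(0L, 10L, p1), "wildtype")  # p = 1
  expect_lt(oracle_bb_tail(6, 10, 0.21, 104.95), 0.01)
  expect_identical(genotype_cell_snv(6L, 4L, p1), "mutated")
  # vectorized
  expect_identical(genotype_cell_snv(c(0L, 0L, 6L), c(0L, 10L, 4L), p1),
                   c("missing", "wildtype", "mutated"))
})

test_that("mitochondrial genotypes use the strict per-cell VAF threshold", {
  expect_identical(genotype_cell_mt(31L, 100L), "mutated")   # VAF 0.31
  expect_identical(genotype_cell_mt(30L, 100L), "wildtype")  # VAF 0.30 exact
  expect_identical(genotype_cell_mt(0L, 0L), "missing")
})

matrix_fixture <- function() {
  pos <- c(100000L, 200000L, 300000L)
  cells <- sprintf("BC%d", 1:6)
  rows <- list()
  cover <- list(`100000` = cells[1:5], `200000` = cells[1:4],
                `300000` = cells[1:5])
  for (p in pos) {
    cvr <- cover[[as.character(p)]]
    rows[[as.character(p)]] <- data.table::data.table(
      chrom = "chr1", pos = p, ref = "A", barcode = cvr,
      A = 5L, C = 0L, G = ifelse(cvr == "BC1", 8L, 0L), T = 0L, other = 0L)
  }
  tab <- base_count_table(data.table::rbindlist(rows),
                          stats::setNames(rep("cancer", 6L), cells))
  snvs <- data.table::data.table(chrom = "chr1", pos = pos, ref = "A",
                                 alt = "G")
  fusions <- data.table::data.table(fusion_name = "AA--BB")
  fcalls <- data.table::data.table(fusion_name = "AA--BB",
                                   barcode = cells[1:3])
  list(tab = tab, snvs = snvs, fusions = fusions, fcalls = fcalls)
}

test_that("matrix row and column coverage filters reach a fixed point", {
  fx <- matrix_fixture()
  m <- build_matrix(snvs = fx$snvs, fusions = fx$fusions,
                    fusion_calls = fx$fcalls, table = fx$tab, params = p1)
  # the SNV covered in only 4 cells is dropped; the 3-cell fusion kept
  expect_setequal(rownames(m), c("chr1:100000:A:G", "chr1:300000:A:G",
                                 "AA--BB"))
  # the cell with < 3 non-missing entries is dropped
  expect_false("BC6" %in% colnames(m))
  expect_setequal(colnames(m), sprintf("BC%d", 1:5))
  # re-applying the filters changes nothing (fixed point)
  md <- attr(m, "metadata")
  non_missing <- rowSums(m != 3L)
  expect_true(all(non_missing[md$type == "SNV"] >= 5L))
  expect_true(all(rowSums(m == 1L)[md$type == "fusion"] >= 3L))
  expect_true(all(colSums(m != 3L) >= 3L))
  # encoding: mutated cell BC1, wildtype others, fusion never missing
  expect_equal(unname(m["chr1:100000:A:G", "BC1"]), 1L)
  expect_equal(unname(m["chr1:100000:A:G", "BC2"]), 0L)
  expect_equal(unname(m["AA--BB", "BC5"]), 0L)
  # a fusion detected in too few cells is dropped
  m2 <- suppressWarnings(build_matrix(snvs = fx$snvs, fusions = fx$fusions,
                                      fusion_calls = fx$fcalls[1:2],
                                      table = fx$tab, params = p1))
  expect_false("AA--BB" %in% rownames(m2))
})

test_that("the matrix TSV round-trips bit-exactly", {
  fx <- matrix_fixture()
  m <- build_matrix(snvs = fx$snvs, fusions = fx$fusions,
                    fusion_calls = fx$fcalls, table = fx$tab, params = p1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_identical(unclass(m)[, ], unclass(back)[, ])
  expect_equal(attr(back, "metadata")$type, attr(m, "metadata")$type)
})

test_that("MCF counts mutated cells among covered cells only", {
  cells <- sprintf("BC%02d", 1:10)
  # 8 covered cells (2 cells absent), 6 clearly mutated
  dt <- data.table::data.table(
    chrom = "chr1", pos = 1000L, ref = "A", barcode = cells[1:8],
    A = c(rep(0L, 6L), 10L, 10L), C = 0L,
    G = c(rep(10L, 6L), 0L, 0L), T = 0L, other = 0L)
  tab <- base_count_table(dt, stats::setNames(rep("cancer", 10L), cells))
  v <- data.table::data.table(chrom = "chr1", pos = 1000L, ref = "A",
                              alt = "G")
  mcf <- compute_mcf(tab, v, cells, p1)
  expect_equal(mcf$n_covered, 8L)
  expect_equal(mcf$mcf, 0.75)
  # no covered cells: 0 with a flag
  mcf0 <- compute_mcf(tab, data.table::data.table(
    chrom = "chr1", pos = 9999L, ref = "A", alt = "G"), cells, p1)
  expect_equal(mcf0$mcf, 0)
  expect_true(mcf0$no_coverage)
  # all covered cells mutated
  mcf1 <- compute_mcf(tab, v, cells[1:6], p1)
  expect_equal(mcf1$mcf, 1)
})

test_that("two planted subclones separate when clustering the matrix", {
  skip_if_not_installed("mclust")
  sim <- cached_sim(21, subclone_fractions = c(0.5, 0.5),
                    subclone_private_sites = c(8L, 8L))
  res <- quiet_pipeline(sim$table, sim$cell_types, sim$resources,
                        sim$fusion_calls)
  m <- res$matrix
  truth_cells <- sim$truth$cells
  cancer_cols <- intersect(colnames(m),
                           truth_cells[truth_cells$true_label == "cancer"]$barcode)
  x <- t(ifelse(m[, cancer_cols, drop = FALSE] == 3L, 0.5,
                m[, cancer_cols, drop = FALSE]))
  set.seed(1)
  km <- stats::kmeans(x, centers = 2L, nstart = 10L)
  truth_sub <- truth_cells$subclone[match(cancer_cols, truth_cells$barcode)]
  ari <- mclust::adjustedRandIndex(km$cluster, truth_sub)
  expect_gte(ari, 0.9)
})
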