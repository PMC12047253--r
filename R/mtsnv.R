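#' Call somatic mitochondrial SNVs
#'
#' Mitochondrial RNA is abundant, heavily mutated, and the dominant
#' component of ambient RNA released by dying cells, so non-cancer
#' cells routinely carry cancer-derived mitochondrial reads at low
#' allele fractions.  The nuclear germline filter would discard such
#' loci wholesale; mitochondrial candidates therefore run a dedicated
#' contamination-robust battery instead: (1) at least `mt_min_depth`
#' (100) aggregated reads in both cancer and non-cancer cells; (2) not
#' at gnomAD frequency >= 1%; (3) delta MCF of at least
#' `mt_min_delta_mcf` (0.35; loci with delta MCF strictly below are
#' filtered, the boundary is retained); (4) cancer VAF of at least
#' `mt_min_vaf_cancer` (0.1; strictly lower fails).  Candidate
#' detection (one alternative read, five reads of cancer coverage) is
#' the implicit first step and is performed upstream by
#' [detect_candidates()] / [build_variant_records()].
#'
#' @param records Candidate records restricted to mitochondrial
#'   contigs, with MCFs/VAFs computed from reannotated labels.
#' @param resources An [annotation_resources()] bundle (any supplied
#'   frequency table is accepted for the gnomAD step).
#' @param thresholds A [calling_thresholds()] list.
#' @return A `call_set` (records + ledger + funnel); `somatic` holds
#'   the called mtSNVs.
#' @export
call_somatic_mtsnvs <- function(records,
                                resources = annotation_resources(),
                                thresholds = calling_thresholds()) {
  records <- data.table::copy(data.table::as.data.table(records))
  th <- thresholds
  if (nrow(records) && !all(records$chrom %in% th$mt_chroms))
    stop("call_somatic_mtsnvs() expects mitochondrial loci only")
  ledger <- list(
    mt_coverage = records$cancer_depth >= th$mt_min_depth &
      records$noncancer_depth >= th$mt_min_depth,
    gnomad = filter_gnomad(records, resources, th),
    delta_mcf = !(records$delta_mcf < th$mt_min_delta_mcf),
    vaf_cancer = !(records$vaf_cancer < th$mt_min_vaf_cancer))
  for (nm in names(ledger)) records[, (paste0("pass_", nm)) := ledger[[nm]]]
  call_set(records, steps = names(ledger))
}

#' Per-cell mitochondrial VAF profiles
#'
#' Per-cell variant allele fractions at called mtSNV loci, split by
#' cell-type group, with group means — the diagnostic used to judge
#' ambient-contamination levels and the per-cell genotyping VAF
#' threshold.
#'
#' @param table A [base_count_table()].
#' @param loci data.frame with `chrom`, `pos`, `alt` (called mtSNVs).
#' @param labels Named character vector `barcode -> label` (defaults
#'   to the table's labels).
#' @return list with `cells` (per-cell VAFs: `chrom`, `pos`, `alt`,
#'   `barcode`, `label`, `depth`, `alt_reads`, `vaf`) and `summary`
#'   (per locus x group mean VAF over covered cells).
#' @export
mt_contamination_profile <- function(table, loci,
                                     labels = cell_labels(table)) {
  loci <- data.table::as.data.table(loci)
  stopifnot(all(c("chrom", "pos", "alt") %in% names(loci)))
  sub <- data.table::as.data.table(table)[barcode %in% names(labels)]
  sub <- merge(loci[, c("chrom", "pos", "alt"), with = FALSE], sub,
               by = c("chrom", "pos"))
  if (!nrow(sub)) {
    return(list(cells = data.table::data.table(
      chrom = character(), pos = integer(), alt = character(),
      barcode = character(), label = character(), depth = integer(),
      alt_reads = integer(), vaf = numeric()),
      summary = data.table::data.table(
        chrom = character(), pos = integer(), alt = character(),
        label = character(), n_cells = integer(), mean_vaf = numeric())))
  }
  sub[, depth := bc_depth(sub)]
  sub[, alt_reads := base_count(sub, alt)]
  sub <- sub[depth >= 1L]
  sub[, vaf := alt_reads / depth]
  sub[, label := labels[barcode]]
  cells <- sub[, c("chrom", "pos", "alt", "barcode", "label", "depth",
                   "alt_reads", "vaf"), with = FALSE]
  summary <- cells[, list(n_cells = .N, mean_vaf = mean(vaf)),
                   by = c("chrom", "pos", "alt", "label")]
  list(cells = cells, summary = summary[])
}
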