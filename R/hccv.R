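#' High-confidence cancer variants and cell-type reannotation
#'
#' Marker-gene cell-type labels can be wrong, and even a small fraction
#' of cancer cells mislabelled as non-cancer pushes true somatic loci
#' into the germline filter.  Before definitive calling, a stringent
#' pre-filter therefore selects high-confidence cancer variants
#' (HCCVs) from the original labels, and each cell is relabelled from
#' its mutational profile over those HCCVs.
#'
#' @name hccv
NULL

hccv_steps_snv <- c("coverage", "other_noise", "homopolymer", "gnomad",
                    "editing", "pon", "vaf_noncancer", "delta_mcf",
                    "distance")

#' Select high-confidence cancer SNVs
#'
#' Candidates (from the original, marker-based labels) are retained
#' when, in order: both pseudo-bulk depths reach `hccv_min_depth`
#' (20); the residual non-reference alleles are not significantly
#' above background (0.05); the locus is not in a homopolymer tract,
#' not at gnomAD frequency >= 1%, not an RNA-editing site, and not in
#' either panel of normals; the non-cancer VAF is below
#' `hccv_max_vaf_noncancer` (0.2) while the cancer-vs-noncancer
#' mutated-cell-fraction difference exceeds `hccv_min_delta_mcf`
#' (0.4, strict); and no other surviving HCCV lies within
#' `min_distance` bp.  A non-zero non-cancer VAF is tolerated
#' deliberately: mislabelled cancer cells put true cancer variants at
#' low non-cancer VAF, and those are exactly the variants that drive
#' reannotation.
#'
#' @param records Candidate records from [build_variant_records()]
#'   under the original labels (nuclear loci).
#' @param resources An [annotation_resources()] bundle.
#' @param params2 Other-allele background [beta_params()].
#' @param thresholds A [calling_thresholds()] list.
#' @return A `call_set` whose `somatic` element holds the HCCVs.
#' @export
select_hccv_snvs <- function(records, resources,
                             params2 = default_beta_params("other"),
                             thresholds = calling_thresholds()) {
  records <- data.table::copy(data.table::as.data.table(records))
  th <- thresholds
  ledger <- list(
    coverage = records$cancer_depth >= th$hccv_min_depth &
      records$noncancer_depth >= th$hccv_min_depth,
    other_noise = filter_other_allele_noise(records, params2, th),
    homopolymer = filter_homopolymer(records, resources, th),
    gnomad = filter_gnomad(records, resources, th),
    editing = filter_editing(records, resources),
    pon = filter_pon(records, resources, "both"),
    vaf_noncancer = records$vaf_noncancer < th$hccv_max_vaf_noncancer,
    delta_mcf = records$delta_mcf > th$hccv_min_delta_mcf)
  for (nm in names(ledger)) records[, (paste0("pass_", nm)) := ledger[[nm]]]
  alive <- if (nrow(records)) Reduce(`&`, ledger) else logical(0)
  dist_pass <- rep(NA, nrow(records))
  if (any(alive)) dist_pass[alive] <- filter_distance(records[alive], th)
  records[, pass_distance := dist_pass]
  call_set(records, steps = hccv_steps_snv)
}

#' Select high-confidence cancer mtSNVs
#'
#' Mitochondrial candidates run the same chain as
#' [select_hccv_snvs()] with two exceptions: the distance rule is not
#' applied (mitochondrial variants legitimately cluster on the 16.6 kb
#' genome) and only the long-read panel of normals is used (the
#' short-read panel does not represent long-read mitochondrial
#' artifacts).
#'
#' @param records Candidate records restricted to mitochondrial
#'   contigs.
#' @inheritParams select_hccv_snvs
#' @return A `call_set` whose `somatic` element holds the mtSNV HCCVs.
#' @export
select_hccv_mtsnvs <- function(records, resources,
                               params2 = default_beta_params("other"),
                               thresholds = calling_thresholds()) {
  records <- data.table::copy(data.table::as.data.table(records))
  th <- thresholds
  ledger <- list(
    coverage = records$cancer_depth >= th$hccv_min_depth &
      records$noncancer_depth >= th$hccv_min_depth,
    other_noise = filter_other_allele_noise(records, params2, th),
    homopolymer = filter_homopolymer(records, resources, th),
    gnomad = filter_gnomad(records, resources, th),
    editing = filter_editing(records, resources),
    pon = filter_pon(records, resources, "lr"),
    vaf_noncancer = records$vaf_noncancer < th$hccv_max_vaf_noncancer,
    delta_mcf = records$delta_mcf > th$hccv_min_delta_mcf)
  for (nm in names(ledger)) records[, (paste0("pass_", nm)) := ledger[[nm]]]
  call_set(records, steps = names(ledger))
}

#' Select high-confidence cancer fusions
#'
#' A fusion is an HCCV when its mutated-cell fraction is above
#' `fusion_min_mcf_cancer` in cancer cells (strict >) and below
#' `fusion_max_mcf_noncancer` in non-cancer cells (strict <).  Fusion
#' MCF denominators are all cells of the type (fusions have no
#' per-cell coverage notion).
#'
#' @param fusion_calls data.frame (`fusion_name`, `barcode`) of
#'   per-cell fusion detections.
#' @param cell_types Named character vector `barcode -> label`.
#' @param thresholds A [calling_thresholds()] list.
#' @return data.table of selected fusions with per-type counts and
#'   MCFs.
#' @export
select_hccv_fusions <- function(fusion_calls, cell_types,
                                thresholds = calling_thresholds()) {
  select_somatic_fusions(fusion_calls, cell_types, thresholds)
}

#' Reannotate cell types from HCCV mutational profiles
#'
#' Each cell is genotyped over the HCCVs (beta-binomial rule for
#' nuclear SNVs, per-cell VAF rule for mtSNVs; fusions count every
#' typed cell as covered and detected cells as mutated).  Cells
#' covering fewer than `reannot_min_covered` HCCVs are labelled
#' `"filtered"` (and later excluded from both pseudo-bulks); cells
#' with at least `reannot_min_fraction` (25%, inclusive) of their
#' covered HCCVs mutated become `"cancer"`, the rest `"noncancer"`.
#'
#' @param table A [base_count_table()].
#' @param hccv_snvs,hccv_mtsnvs data.frames of HCCV loci (`chrom`,
#'   `pos`, `ref`, `alt`); may be empty.
#' @param hccv_fusions data.frame of selected fusions (`fusion_name`).
#' @param fusion_calls data.frame (`fusion_name`, `barcode`).
#' @param params1 Primary background [beta_params()].
#' @param thresholds A [calling_thresholds()] list.
#' @return data.table with `barcode`, `old_label`, `new_label`,
#'   `n_covered`, `n_mutated`, `fraction`.
#' @export
reannotate_cells <- function(table, hccv_snvs = NULL, hccv_mtsnvs = NULL,
                             hccv_fusions = NULL, fusion_calls = NULL,
                             params1 = default_beta_params("primary"),
                             thresholds = calling_thresholds()) {
  labels <- attr(table, "cell_types")
  cells <- names(labels)
  th <- thresholds
  vars <- data.table::rbindlist(list(
    if (!is.null(hccv_snvs) && nrow(data.table::as.data.table(hccv_snvs)))
      data.table::as.data.table(hccv_snvs)[, c("chrom", "pos", "ref", "alt"), with = FALSE],
    if (!is.null(hccv_mtsnvs) && nrow(data.table::as.data.table(hccv_mtsnvs)))
      data.table::as.data.table(hccv_mtsnvs)[, c("chrom", "pos", "ref", "alt"), with = FALSE]))
  cov <- mut <- stats::setNames(integer(length(cells)), cells)
  if (!is.null(vars) && nrow(vars)) {
    gt <- genotype_cells(table, vars, params1, level = th$genotype_level,
                         mt_vaf_threshold = th$mt_genotype_vaf,
                         barcodes = cells, mt_chroms = th$mt_chroms)
    tal <- gt[, list(cov = sum(depth >= 1L),
                     mut = sum(depth >= 1L & genotype == "mutated")),
              by = "barcode"]
    cov[tal$barcode] <- tal$cov
    mut[tal$barcode] <- tal$mut
  }
  if (!is.null(hccv_fusions) && nrow(data.table::as.data.table(hccv_fusions))) {
    fus <- data.table::as.data.table(hccv_fusions)
    calls <- unique(data.table::as.data.table(fusion_calls)[
      fusion_name %in% fus$fusion_name, c("fusion_name", "barcode"), with = FALSE])
    cov <- cov + nrow(fus)  # every typed cell is "covered" for a fusion
    det <- calls[barcode %in% cells, list(n = .N), by = "barcode"]
    mut[det$barcode] <- mut[det$barcode] + det$n
  }
  frac <- ifelse(cov > 0L, mut / cov, 0)
  new_label <- ifelse(cov < th$reannot_min_covered, "filtered",
                      ifelse(frac >= th$reannot_min_fraction,
                             "cancer", "noncancer"))
  data.table::data.table(barcode = cells, old_label = unname(labels),
                         new_label = new_label, n_covered = unname(cov),
                         n_mutated = unname(mut), fraction = unname(frac))
}

#' Reannotation confusion matrix
#'
#' Cross-tabulates original versus reannotated labels (the shape used
#' to audit how many cells changed class).
#'
#' @param reannotation Output of [reannotate_cells()].
#' @return data.table cross-tabulation with cell counts and fractions.
#' @export
reannotation_summary <- function(reannotation) {
  out <- data.table::as.data.table(reannotation)[
    , list(n = .N), by = c("old_label", "new_label")]
  out[, fraction := n / sum(n)]
  out[]
}
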