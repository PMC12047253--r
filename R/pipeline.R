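#' Run the two-pass calling workflow
#'
#' Pass 1 builds candidate records under the original (marker-based)
#' labels, selects high-confidence cancer variants (SNVs, mtSNVs,
#' fusions) and reannotates every cell from its HCCV mutational
#' profile.  Pass 2 rebuilds pseudo-bulks from the reannotated labels
#' (cells labelled `"filtered"` are excluded from both) and performs
#' definitive calling: the 10-step nuclear SNV battery, the
#' contamination-robust mitochondrial battery, fusion selection, and
#' the cell-by-variant genotype matrix for clonal reconstruction.
#' With `reannotate = FALSE` the first pass is skipped and calling
#' runs once on the original labels (the configuration used for A/B
#' comparisons of the reannotation step).
#'
#' @param table A [base_count_table()].
#' @param cell_types Named character vector `barcode -> label`
#'   (original annotation; defaults to the table's labels).
#' @param resources An [annotation_resources()] bundle.
#' @param fusion_calls Optional data.frame (`fusion_name`, `barcode`).
#' @param params1,params2 Primary / other-allele [beta_params()].
#' @param thresholds A [calling_thresholds()] list.
#' @param reannotate Run the HCCV reannotation pass.
#' @param out_dir Optional output directory; when given, all result
#'   tables are written there (VCF + TSV calls, funnel, reannotation,
#'   fusion and matrix TSVs, thresholds YAML).
#' @param scwgs Optional [clone_counts()] for validation; adds
#'   scWGS support labels and performance metrics to the result.
#' @param scwgs_cell_alt Optional per-aneuploid-cell alternative
#'   counts for the de novo scWGS truth set.
#' @param verbose Emit per-stage progress messages.
#' @return A `pipeline_result` list: `labels` (labels used for
#'   definitive calling), `reannotation`, `hccv`, `snv` (`call_set`),
#'   `mt` (`call_set`), `fusions`, `matrix`, and (with scWGS input)
#'   `scwgs_support`, `scwgs_truth`, `scwgs_performance`.
#' @export
run_pipeline <- function(table, cell_types = cell_labels(table),
                         resources = annotation_resources(),
                         fusion_calls = NULL,
                         params1 = default_beta_params("primary"),
                         params2 = default_beta_params("other"),
                         thresholds = calling_thresholds(),
                         reannotate = TRUE, out_dir = NULL,
                         scwgs = NULL, scwgs_cell_alt = NULL,
                         verbose = FALSE) {
  th <- thresholds
  labels0 <- normalize_cell_types(cell_types)
  say <- function(...) if (verbose) message(...)
  check_scale_guardrails(table, labels0, th)

  reanno <- NULL; hccv <- NULL
  if (reannotate) {
    say("pass 1: candidate records under original labels")
    rec0 <- build_variant_records(table, labels0, params1, th)
    nuc0 <- rec0[!chrom %in% th$mt_chroms]
    mt0 <- rec0[chrom %in% th$mt_chroms]
    say("pass 1: selecting high-confidence cancer variants")
    hccv_snv <- select_hccv_snvs(nuc0, resources, params2, th)
    hccv_mt <- select_hccv_mtsnvs(mt0, resources, params2, th)
    hccv_fus <- if (!is.null(fusion_calls))
      select_hccv_fusions(fusion_calls, labels0, th) else NULL
    hccv <- list(snvs = hccv_snv$somatic, mtsnvs = hccv_mt$somatic,
                 fusions = hccv_fus)
    say(sprintf("pass 1: %d HCCV SNVs, %d HCCV mtSNVs, %d HCCV fusions",
                nrow(hccv$snvs), nrow(hccv$mtsnvs),
                if (is.null(hccv_fus)) 0L else nrow(hccv_fus)))
    reanno <- reannotate_cells(table, hccv$snvs, hccv$mtsnvs, hccv_fus,
                               fusion_calls, params1, th)
    labels <- stats::setNames(reanno$new_label, reanno$barcode)
    say(sprintf("pass 1: reannotated %d cells (%d cancer, %d noncancer, %d filtered)",
                length(labels), sum(labels == "cancer"),
                sum(labels == "noncancer"), sum(labels == "filtered")))
  } else {
    labels <- labels0
  }

  say("pass 2: definitive calling on ",
      if (reannotate) "reannotated" else "original", " labels")
  rec <- build_variant_records(table, labels, params1, th)
  nuc <- rec[!chrom %in% th$mt_chroms]
  mtc <- rec[chrom %in% th$mt_chroms]
  snv <- call_somatic_snvs(table, labels, resources, params1, params2, th,
                           records = nuc)
  mt <- call_somatic_mtsnvs(mtc, resources, th)
  fus <- if (!is.null(fusion_calls))
    select_somatic_fusions(fusion_calls, labels, th) else NULL
  say(sprintf("pass 2: %d somatic SNVs, %d somatic mtSNVs, %d somatic fusions",
              nrow(snv$somatic), nrow(mt$somatic),
              if (is.null(fus)) 0L else nrow(fus)))

  typed <- labels[labels %in% c("cancer", "noncancer")]
  tab2 <- table
  if (length(typed) < length(labels)) {
    keep <- data.table::as.data.table(table)[barcode %in% c(names(typed), attr(table, "droplets"))]
    tab2 <- base_count_table(keep, typed, droplets = attr(table, "droplets"),
                             min_mq = attr(table, "min_mq"))
  } else {
    tab2 <- base_count_table(data.table::as.data.table(table), typed,
                             droplets = attr(table, "droplets"),
                             min_mq = attr(table, "min_mq"))
  }
  mat <- suppressWarnings(build_matrix(
    snvs = snv$somatic, mtsnvs = mt$somatic, fusions = fus,
    fusion_calls = fusion_calls, table = tab2, params = params1,
    level = th$genotype_level, mt_vaf_threshold = th$mt_genotype_vaf,
    min_cells_snv = th$matrix_min_cells_snv,
    min_cells_fusion = th$matrix_min_cells_fusion,
    min_variants_cell = th$matrix_min_variants_cell,
    mt_chroms = th$mt_chroms))

  res <- list(labels = labels, reannotation = reanno, hccv = hccv,
              snv = snv, mt = mt, fusions = fus, matrix = mat,
              thresholds = th)
  if (!is.null(scwgs)) {
    calls <- data.table::rbindlist(list(
      snv$somatic[, c("chrom", "pos", "ref", "alt"), with = FALSE],
      mt$somatic[, c("chrom", "pos", "ref", "alt"), with = FALSE]))
    res$scwgs_support <- classify_support(calls, scwgs, params1, th)
    cancer_pb <- aggregate_pseudobulk(table, names(labels)[labels == "cancer"],
                                      "cancer")
    noncancer_pb <- aggregate_pseudobulk(table,
                                         names(labels)[labels == "noncancer"],
                                         "noncancer")
    res$scwgs_truth <- call_scwgs_denovo(scwgs, cancer_pb, noncancer_pb,
                                         params1, scwgs_cell_alt, th)
    truth_somatic <- res$scwgs_truth[somatic == TRUE]
    res$scwgs_performance <- performance(
      calls, truth_somatic,
      eligible = res$scwgs_truth[, c("chrom", "pos"), with = FALSE])
  }
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# the recommended operating scale; violations warn, never abort
check_scale_guardrails <- function(table, labels, th) {
  dt <- data.table::as.data.table(table)
  if (!nrow(dt)) return(invisible(NULL))
  for (lab in c("cancer", "noncancer")) {
    bcs <- names(labels)[labels == lab]
    sub <- dt[barcode %in% bcs]
    if (!nrow(sub)) next
    total <- sum(bc_depth(sub))
    if (total < 2e9)
      warning("only ", format(total, big.mark = ","), " aggregated bases in ",
              lab, " cells; recommended operating scale is >= 2 billion ",
              "mapped bases per cell type", call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  if (!is.null(x$reannotation)) {
    cat(sprintf("  reannotation: %d cells -> %d cancer / %d noncancer / %d filtered\n",
                nrow(x$reannotation), sum(x$labels == "cancer"),
                sum(x$labels == "noncancer"), sum(x$labels == "filtered")))
  }
  cat(sprintf("  somatic SNVs: %d of %d candidates\n",
              nrow(x$snv$somatic), nrow(x$snv$records)))
  cat(sprintf("  somatic mtSNVs: %d of %d candidates\n",
              nrow(x$mt$somatic), nrow(x$mt$records)))
  if (!is.null(x$fusions))
    cat(sprintf("  somatic fusions: %d\n", nrow(x$fusions)))
  cat(sprintf("  cell-variant matrix: %d x %d\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$scwgs_performance))
    cat(sprintf("  scWGS benchmark: precision %.3f, sensitivity %.3f, F1 %.3f\n",
                x$scwgs_performance$precision,
                x$scwgs_performance$sensitivity, x$scwgs_performance$f1))
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_call_vcf(res$snv, p("somatic_snvs.vcf"))
  write_call_vcf(res$mt, p("somatic_mtsnvs.vcf"), mt = TRUE)
  data.table::fwrite(res$snv$somatic, p("somatic_snvs.tsv"), sep = "\t")
  data.table::fwrite(res$mt$somatic, p("somatic_mtsnvs.tsv"), sep = "\t")
  write_funnel(res$snv$funnel, p("snv_funnel.tsv"))
  write_funnel(res$mt$funnel, p("mtsnv_funnel.tsv"))
  if (!is.null(res$reannotation)) {
    data.table::fwrite(res$reannotation, p("reannotation.tsv"), sep = "\t")
    data.table::fwrite(reannotation_summary(res$reannotation),
                       p("reannotation_confusion.tsv"), sep = "\t")
  }
  if (!is.null(res$fusions))
    data.table::fwrite(res$fusions, p("somatic_fusions.tsv"), sep = "\t")
  write_matrix(res$matrix, p("cell_variant_matrix.tsv"))
  th <- res$thresholds
  yaml::write_yaml(th[!vapply(th, is.character, logical(1L)) |
                        names(th) == "mt_chroms"], p("thresholds.yaml"))
  if (!is.null(res$scwgs_support))
    data.table::fwrite(res$scwgs_support, p("scwgs_support.tsv"), sep = "\t")
  if (!is.null(res$scwgs_performance))
    jsonlite::write_json(res$scwgs_performance, p("scwgs_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Score pipeline calls against a synthetic truth set
#'
#' Convenience evaluation of a [run_pipeline()] result on a
#' [simulate_dataset()] truth: nuclear somatic sensitivity/precision,
#' germline leakage into the final call set, and mitochondrial recall.
#'
#' @param result A `pipeline_result`.
#' @param truth The `truth` element of a `sim_dataset`.
#' @return list with `snv` (performance list), `n_germline_called`,
#'   `mt_sensitivity`.
#' @export
evaluate_calls <- function(result, truth) {
  sites <- data.table::as.data.table(truth$sites)
  som <- sites[class == "somatic"]
  germ <- sites[class == "germline"]
  mt <- sites[class == "mt_somatic"]
  calls <- result$snv$somatic
  perf <- performance(calls, som)
  key <- function(x) paste(x$chrom, x$pos)
  n_germ <- length(intersect(key(calls), key(germ)))
  mt_sens <- if (nrow(mt))
    length(intersect(key(result$mt$somatic), key(mt))) / nrow(mt) else NA_real_
  list(snv = perf, n_germline_called = n_germ, mt_sensitivity = mt_sens)
}
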