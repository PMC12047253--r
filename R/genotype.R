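#' Single-cell genotype at a nuclear SNV
#'
#' A cell is called mutated when the one-sided beta-binomial test on
#' its alternative-allele reads against its reference-allele reads is
#' significant at the (strict) 0.01 level; missing when it has no
#' alt or ref reads at the locus.
#'
#' @param alt_reads,ref_reads Integer vectors of per-cell read counts.
#' @param params Background-error [beta_params()].
#' @param level Significance level (strict).
#' @return Character vector in `{"mutated", "wildtype", "missing"}`.
#' @export
genotype_cell_snv <- function(alt_reads, ref_reads, params, level = 0.01) {
  n <- alt_reads + ref_reads
  out <- rep("wildtype", length(n))
  out[n == 0L] <- "missing"
  idx <- which(n > 0L)
  if (length(idx)) {
    sig <- is_significant(alt_reads[idx], n[idx], params, level)
    out[idx][sig] <- "mutated"
  }
  out
}

#' Single-cell genotype at a mitochondrial SNV
#'
#' Ambient cancer mtRNA contaminates non-cancer cells at low allele
#' fractions, so mitochondrial genotypes use a hard per-cell VAF
#' threshold instead of the error-model test: mutated iff
#' `alt/depth > vaf_threshold` (strict).
#'
#' @param alt_reads,depth Integer vectors of per-cell counts.
#' @param vaf_threshold Per-cell VAF above which the cell is mutated.
#' @return Character vector in `{"mutated", "wildtype", "missing"}`.
#' @export
genotype_cell_mt <- function(alt_reads, depth, vaf_threshold = 0.3) {
  out <- rep("wildtype", length(depth))
  out[depth == 0L] <- "missing"
  idx <- which(depth > 0L)
  out[idx][alt_reads[idx] / depth[idx] > vaf_threshold] <- "mutated"
  out
}

variant_id <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Genotype every cell at a set of variants
#'
#' Long-format per-cell genotypes over SNV/mtSNV loci.  Mitochondrial
#' loci (recognized by `mt_chroms`) use the per-cell VAF rule, nuclear
#' loci the beta-binomial test.  Cells of the table with no row at a
#' locus are reported missing.
#'
#' @param table A [base_count_table()].
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param params Background-error [beta_params()].
#' @param level Nuclear genotyping significance level (strict).
#' @param mt_vaf_threshold Mitochondrial per-cell VAF threshold.
#' @param barcodes Cells to genotype (default: all typed cells).
#' @param mt_chroms Contig names treated as mitochondrial.
#' @return data.table with `variant`, `chrom`, `pos`, `barcode`,
#'   `alt_reads`, `ref_reads`, `depth`, `genotype`.
#' @export
genotype_cells <- function(table, variants, params, level = 0.01,
                           mt_vaf_threshold = 0.3,
                           barcodes = names(attr(table, "cell_types")),
                           mt_chroms = c("chrM", "MT", "chrMT")) {
  variants <- data.table::as.data.table(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!nrow(variants))
    return(data.table::data.table(variant = character(), chrom = character(),
                                  pos = integer(), barcode = character(),
                                  alt_reads = integer(), ref_reads = integer(),
                                  depth = integer(), genotype = character()))
  vv <- variants[, c("chrom", "pos", "ref", "alt"), with = FALSE]
  vv[, variant := variant_id(vv)]
  grid <- vv[, list(barcode = barcodes), by = c("variant", "chrom", "pos", "ref", "alt")]
  sub <- data.table::as.data.table(table)[barcode %in% barcodes]
  sub <- merge(grid, sub, by = c("chrom", "pos", "ref", "barcode"),
               all.x = TRUE)
  for (b in c("A", "C", "G", "T", "other"))
    data.table::set(sub, which(is.na(sub[[b]])), b, 0L)
  sub[, depth := bc_depth(sub)]
  sub[, alt_reads := base_count(sub, alt)]
  sub[, ref_reads := base_count(sub, ref)]
  is_mt <- sub$chrom %in% mt_chroms
  gt <- character(nrow(sub))
  if (any(is_mt))
    gt[is_mt] <- genotype_cell_mt(sub$alt_reads[is_mt], sub$depth[is_mt],
                                  vaf_threshold = mt_vaf_threshold)
  if (any(!is_mt))
    gt[!is_mt] <- genotype_cell_snv(sub$alt_reads[!is_mt],
                                    sub$ref_reads[!is_mt], params,
                                    level = level)
  sub[, genotype := gt]
  sub[, c("variant", "chrom", "pos", "barcode", "alt_reads", "ref_reads",
          "depth", "genotype"), with = FALSE]
}

#' Mutated cell fraction
#'
#' Fraction of mutated cells within a group, counting only cells with
#' at least one read at the position.  Returns 0 (flagged) when no
#' group cell covers the locus.
#'
#' @inheritParams genotype_cells
#' @param group Character vector of member barcodes.
#' @return data.table with `variant`, `n_covered`, `n_mutated`, `mcf`,
#'   `no_coverage` (flag).
#' @export
compute_mcf <- function(table, variants, group, params, level = 0.01,
                        mt_vaf_threshold = 0.3,
                        mt_chroms = c("chrM", "MT", "chrMT")) {
  gt <- genotype_cells(table, variants, params, level = level,
                       mt_vaf_threshold = mt_vaf_threshold,
                       barcodes = group, mt_chroms = mt_chroms)
  variants <- data.table::as.data.table(variants)
  ids <- variant_id(variants)
  out <- gt[, list(n_covered = sum(depth >= 1L),
                   n_mutated = sum(depth >= 1L & genotype == "mutated")),
            by = "variant"]
  out <- out[match(ids, variant)]
  out[, variant := ids]
  out[is.na(n_covered), `:=`(n_covered = 0L, n_mutated = 0L)]
  out[, no_coverage := n_covered == 0L]
  out[, mcf := ifelse(n_covered > 0L, n_mutated / n_covered, 0)]
  out[]
}

#' Cell-by-variant genotype matrix for clonal reconstruction
#'
#' Genotypes every typed cell at the called SNVs, mtSNVs and fusions,
#' then applies the coverage filters used before clonal clustering:
#' SNV/mtSNV rows must be non-missing in at least `min_cells_snv`
#' cells, fusion rows detected in at least `min_cells_fusion` cells;
#' cells with fewer than `min_variants_cell` non-missing entries are
#' dropped.  Rows are re-checked after the column filter until a fixed
#' point is reached.  Entries are encoded 1 = mutated, 0 = wildtype,
#' 3 = missing; fusion entries are never missing.
#'
#' @param snvs,mtsnvs data.frames of called variants (`chrom`, `pos`,
#'   `ref`, `alt`); either may be empty or `NULL`.
#' @param fusions data.frame of selected fusions with a `fusion_name`
#'   column, or `NULL`.
#' @param fusion_calls data.frame (`fusion_name`, `barcode`) of
#'   per-cell fusion detections.
#' @inheritParams genotype_cells
#' @param min_cells_snv,min_cells_fusion,min_variants_cell Row/column
#'   coverage thresholds (inclusive).
#' @return An object of class `cell_variant_matrix`: an integer matrix
#'   (variants x cells) with attributes `metadata` (per-row type) and
#'   `encoding`.
#' @export
build_matrix <- function(snvs, mtsnvs = NULL, fusions = NULL,
                         fusion_calls = NULL, table, params,
                         level = 0.01, mt_vaf_threshold = 0.3,
                         min_cells_snv = 5L, min_cells_fusion = 3L,
                         min_variants_cell = 3L,
                         mt_chroms = c("chrM", "MT", "chrMT")) {
  cells <- names(attr(table, "cell_types"))
  vlist <- data.table::rbindlist(list(
    if (!is.null(snvs) && nrow(data.table::as.data.table(snvs)))
      data.table::as.data.table(snvs)[, c("chrom", "pos", "ref", "alt"), with = FALSE],
    if (!is.null(mtsnvs) && nrow(data.table::as.data.table(mtsnvs)))
      data.table::as.data.table(mtsnvs)[, c("chrom", "pos", "ref", "alt"), with = FALSE]))
  rows <- list(); types <- character(0)
  if (!is.null(vlist) && nrow(vlist)) {
    gt <- genotype_cells(table, vlist, params, level = level,
                         mt_vaf_threshold = mt_vaf_threshold,
                         barcodes = cells, mt_chroms = mt_chroms)
    code <- c(mutated = 1L, wildtype = 0L, missing = 3L)
    wide <- data.table::dcast(gt, variant ~ barcode,
                              value.var = "genotype",
                              fill = "missing")
    ids <- wide$variant
    m <- apply(as.matrix(wide[, -1L, with = FALSE]), 2L, function(col) code[col])
    m <- matrix(as.integer(m), nrow = length(ids),
                dimnames = list(ids, names(wide)[-1L]))
    m <- m[, cells, drop = FALSE]
    rows <- c(rows, list(m))
    types <- c(types, ifelse(vlist$chrom[match(ids, variant_id(vlist))] %in% mt_chroms,
                             "mtSNV", "SNV"))
  }
  if (!is.null(fusions) && nrow(data.table::as.data.table(fusions))) {
    fus <- data.table::as.data.table(fusions)
    calls <- unique(data.table::as.data.table(fusion_calls)[
      , c("fusion_name", "barcode"), with = FALSE])
    fm <- matrix(0L, nrow = nrow(fus), ncol = length(cells),
                 dimnames = list(fus$fusion_name, cells))
    hit <- calls[fusion_name %in% fus$fusion_name & barcode %in% cells]
    if (nrow(hit))
      fm[cbind(match(hit$fusion_name, fus$fusion_name),
               match(hit$barcode, cells))] <- 1L
    rows <- c(rows, list(fm))
    types <- c(types, rep("fusion", nrow(fus)))
  }
  if (!length(rows)) {
    warning("no variants to genotype: returning an empty matrix")
    m <- matrix(integer(0), nrow = 0L, ncol = length(cells),
                dimnames = list(NULL, cells))
    return(new_cell_variant_matrix(m, character(0)))
  }
  m <- do.call(rbind, rows)

  repeat {
    non_missing <- rowSums(m != 3L)
    detected <- rowSums(m == 1L)
    keep_row <- ifelse(types == "fusion",
                       detected >= min_cells_fusion,
                       non_missing >= min_cells_snv)
    m <- m[keep_row, , drop = FALSE]; types <- types[keep_row]
    keep_col <- colSums(m != 3L) >= min_variants_cell
    changed <- !all(keep_row) || !all(keep_col)
    m <- m[, keep_col, drop = FALSE]
    if (!changed || nrow(m) == 0L || ncol(m) == 0L) break
  }
  if (nrow(m) == 0L || ncol(m) == 0L)
    warning("cell-variant matrix is empty after coverage filtering")
  new_cell_variant_matrix(m, types)
}

new_cell_variant_matrix <- function(m, types) {
  structure(m,
            metadata = data.table::data.table(variant = rownames(m),
                                              type = types),
            encoding = c(mutated = 1L, wildtype = 0L, missing = 3L),
            class = c("cell_variant_matrix", "matrix", "array"))
}

#' @export
print.cell_variant_matrix <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf(
    "cell_variant_matrix: %d variants (%d SNV, %d mtSNV, %d fusion) x %d cells\n",
    nrow(x), sum(md$type == "SNV"), sum(md$type == "mtSNV"),
    sum(md$type == "fusion"), ncol(x)))
  cat("encoding: 1 = mutated, 0 = wildtype, 3 = missing\n")
  invisible(x)
}

#' Read / write the cell-variant matrix TSV
#'
#' Variants x cells, `variant` in the first column, one cell per
#' further column, entries 1/0/3 as documented in the header comment;
#' round-trips bit-exactly.  A sidecar `<path>.variants.tsv` carries
#' per-row variant types.
#'
#' @param m A `cell_variant_matrix`.
#' @param path Output TSV path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   a `cell_variant_matrix`.
#' @export
write_matrix <- function(m, path) {
  md <- attr(m, "metadata")
  dt <- data.table::data.table(variant = rownames(m))
  if (ncol(m)) dt <- cbind(dt, data.table::as.data.table(unclass(m)))
  header <- "# cell-variant matrix: 1 = mutated, 0 = wildtype, 3 = missing"
  writeLines(header, path)
  suppressWarnings(
    data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                       col.names = TRUE))
  data.table::fwrite(md, paste0(path, ".variants.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE)
  ids <- dt$variant
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  md_path <- paste0(path, ".variants.tsv")
  types <- if (file.exists(md_path))
    data.table::fread(md_path)$type else rep(NA_character_, nrow(m))
  new_cell_variant_matrix(m, types)
}
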