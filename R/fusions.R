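#' Read a per-cell fusion call table
#'
#' Tab-separated output of an external single-cell fusion detector.
#' The minimum dialect is two columns naming the fusion
#' (`GENEA--GENEB`) and the cell barcode; common alternative column
#' names (`FusionName`/`#FusionName`, `cell_barcode`/`barcodes`) are
#' recognized.  Duplicate (fusion, cell) rows collapse to one
#' detection; extra columns are passed through.
#'
#' @param path TSV file path.
#' @return data.table with at least `fusion_name` and `barcode`.
#' @export
read_fusion_calls <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  nm <- names(dt)
  fcol <- nm[tolower(gsub("^#", "", nm)) %in%
               c("fusion_name", "fusionname", "fusion")][1L]
  bcol <- nm[tolower(nm) %in% c("barcode", "cell_barcode", "barcodes",
                                "cell")][1L]
  if (is.na(fcol) || is.na(bcol))
    stop("fusion table needs fusion-name and cell-barcode columns: ", path)
  data.table::setnames(dt, c(fcol, bcol), c("fusion_name", "barcode"))
  unique(dt, by = c("fusion_name", "barcode"))[]
}

fusion_mcf <- function(fusion_calls, cell_types) {
  ct <- normalize_cell_types(cell_types)
  calls <- unique(data.table::as.data.table(fusion_calls)[
    , c("fusion_name", "barcode"), with = FALSE])
  unknown <- setdiff(unique(calls$barcode), names(ct))
  if (length(unknown)) {
    warning(length(unknown), " fusion barcodes absent from cell_types; ",
            "ignored")
    calls <- calls[!barcode %in% unknown]
  }
  calls[, label := ct[barcode]]
  calls <- calls[label %in% c("cancer", "noncancer")]
  n_cancer_cells <- sum(ct == "cancer")
  n_noncancer_cells <- sum(ct == "noncancer")
  out <- calls[, list(n_cancer = sum(label == "cancer"),
                      n_noncancer = sum(label == "noncancer")),
               by = "fusion_name"]
  out[, mcf_cancer := if (n_cancer_cells > 0) n_cancer / n_cancer_cells else 0]
  out[, mcf_noncancer := if (n_noncancer_cells > 0)
    n_noncancer / n_noncancer_cells else 0]
  out[]
}

#' Select somatic fusions
#'
#' A fusion is somatic when present in more than
#' `fusion_min_mcf_cancer` (5%, strict >) of the cancer cells and in
#' fewer than `fusion_max_mcf_noncancer` (1%, strict <) of the
#' non-cancer cells.  The non-cancer tolerance is deliberate:
#' non-cancer cells can carry fusion reads from ambient cancer RNA.
#' MCF denominators are all cells of the type; labels should be the
#' reannotated ones.  Output is independent of input row order and
#' duplicate (fusion, cell) rows count once.
#'
#' @param fusion_calls data.frame (`fusion_name`, `barcode`); barcodes
#'   absent from `cell_types` are ignored with a warning.
#' @param cell_types Named character vector `barcode -> label`.
#' @param thresholds A [calling_thresholds()] list.
#' @return data.table of selected fusions: `fusion_name`, `n_cancer`,
#'   `n_noncancer`, `mcf_cancer`, `mcf_noncancer`.
#' @export
select_somatic_fusions <- function(fusion_calls, cell_types,
                                   thresholds = calling_thresholds()) {
  mcf <- fusion_mcf(fusion_calls, cell_types)
  if (!nrow(mcf)) return(mcf)
  out <- mcf[mcf_cancer > thresholds$fusion_min_mcf_cancer &
               mcf_noncancer < thresholds$fusion_max_mcf_noncancer]
  data.table::setorder(out, fusion_name)
  out[]
}
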