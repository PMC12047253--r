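#' Annotation resources for variant filtering
#'
#' Bundles the external site lists consumed by the filter battery:
#' population allele frequencies, RNA-editing sites, short-read and
#' long-read panels of normals, and homopolymer tracts derived from the
#' reference.
#'
#' @param gnomad data.frame with columns `chrom`, `pos`, `alt`, `af`
#'   (population allele frequency in `[0, 1]`).
#' @param editing data.frame of RNA-editing sites (`chrom`, `pos`).
#' @param pon_sr,pon_lr data.frames of panel-of-normals loci
#'   (`chrom`, `pos`).
#' @param homopolymers data.frame of mononucleotide tracts (`chrom`,
#'   `start`, `end`, `base`), 1-based half-open `[start, end)`.
#' @return An object of class `annotation_resources`.
#' @export
annotation_resources <- function(gnomad = NULL, editing = NULL,
                                 pon_sr = NULL, pon_lr = NULL,
                                 homopolymers = NULL) {
  as_sites <- function(x) {
    if (is.null(x))
      return(data.table::data.table(chrom = character(), pos = integer()))
    x <- data.table::as.data.table(x)
    stopifnot(all(c("chrom", "pos") %in% names(x)))
    unique(x[, list(chrom = as.character(chrom), pos = as.integer(pos))])
  }
  if (is.null(gnomad)) {
    gnomad <- data.table::data.table(chrom = character(), pos = integer(),
                                     alt = character(), af = numeric())
  } else {
    gnomad <- data.table::as.data.table(gnomad)
    stopifnot(all(c("chrom", "pos", "alt", "af") %in% names(gnomad)))
    gnomad <- gnomad[, list(chrom = as.character(chrom), pos = as.integer(pos),
                            alt = as.character(alt), af = as.numeric(af))]
    if (nrow(gnomad) && (any(gnomad$af < 0) || any(gnomad$af > 1)))
      stop("gnomAD allele frequencies must lie in [0, 1]")
  }
  if (is.null(homopolymers)) {
    homopolymers <- data.table::data.table(chrom = character(),
                                           start = integer(), end = integer(),
                                           base = character())
  } else {
    homopolymers <- data.table::as.data.table(homopolymers)
    stopifnot(all(c("chrom", "start", "end", "base") %in% names(homopolymers)))
  }
  structure(list(gnomad = gnomad, editing = as_sites(editing),
                 pon_sr = as_sites(pon_sr), pon_lr = as_sites(pon_lr),
                 homopolymers = homopolymers),
            class = "annotation_resources")
}

#' @export
print.annotation_resources <- function(x, ...) {
  cat(sprintf(paste0(
    "annotation_resources: %d gnomAD records, %d editing sites, ",
    "%d SR-PoN loci, %d LR-PoN loci, %d homopolymer tracts\n"),
    nrow(x$gnomad), nrow(x$editing), nrow(x$pon_sr), nrow(x$pon_lr),
    nrow(x$homopolymers)))
  invisible(x)
}

#' Load annotation resources from files
#'
#' Reads the standard external formats into an
#' [annotation_resources()] bundle.  Population frequencies come from a
#' VCF (with an `AF` INFO field, read via VariantAnnotation) or a
#' 4-column TSV (`chrom pos alt af`); editing sites and panels of
#' normals from 3-column BED (0-based half-open) or `chrom pos` TSV;
#' homopolymer tracts are computed from the reference FASTA as maximal
#' mononucleotide runs of length at least `tract_min`.  Missing
#' optional resources yield empty sets with a warning.
#'
#' @param gnomad_path,editing_path,pon_sr_path,pon_lr_path File paths
#'   (or `NULL`).
#' @param reference Reference FASTA path, `DNAStringSet`, or named
#'   character vector (or `NULL` to skip homopolymer detection).
#' @param tract_min Minimum run length defining a homopolymer tract.
#' @return An [annotation_resources()] object.
#' @export
load_resources <- function(gnomad_path = NULL, editing_path = NULL,
                           pon_sr_path = NULL, pon_lr_path = NULL,
                           reference = NULL, tract_min = 4L) {
  warn_missing <- function(what) {
    warning("no ", what, " resource supplied: using an empty set")
    NULL
  }
  gnomad <- if (is.null(gnomad_path)) warn_missing("gnomAD") else
    read_gnomad(gnomad_path)
  editing <- if (is.null(editing_path)) warn_missing("RNA-editing") else
    read_site_list(editing_path)
  pon_sr <- if (is.null(pon_sr_path)) warn_missing("SR panel-of-normals") else
    read_site_list(pon_sr_path)
  pon_lr <- if (is.null(pon_lr_path)) warn_missing("LR panel-of-normals") else
    read_site_list(pon_lr_path)
  homopolymers <- if (is.null(reference)) NULL else
    find_homopolymers(reference, tract_min = tract_min)
  annotation_resources(gnomad = gnomad, editing = editing, pon_sr = pon_sr,
                       pon_lr = pon_lr, homopolymers = homopolymers)
}

read_gnomad <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading gnomAD from VCF requires the VariantAnnotation package; ",
           "supply a 4-column TSV instead")
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    af <- VariantAnnotation::info(vcf)$AF
    if (is.null(af)) stop("VCF lacks an AF INFO field: ", path)
    alt <- VariantAnnotation::alt(vcf)
    # expand multi-allelic records
    n_alt <- S4Vectors::elementNROWS(alt)
    af <- unlist(lapply(af, function(v) as.numeric(v)))
    out <- data.table::data.table(
      chrom = rep(as.character(GenomicRanges::seqnames(rr)), n_alt),
      pos = rep(GenomicRanges::start(rr), n_alt),
      alt = as.character(unlist(alt)),
      af = af)
    return(out)
  }
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 4L)
    stop("gnomAD TSV needs 4 columns (chrom, pos, alt, af): ", path)
  data.table::setnames(dt, 1:4, c("chrom", "pos", "alt", "af"))
  pos <- suppressWarnings(as.integer(dt$pos))
  af <- suppressWarnings(as.numeric(dt$af))
  bad <- which(is.na(pos) | is.na(af))
  if (length(bad))
    stop("malformed gnomAD record at line ", bad[1L] + 1L, " of ", path)
  data.table::data.table(chrom = as.character(dt$chrom), pos = pos,
                         alt = as.character(dt$alt), af = af)
}

read_site_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first))
    return(data.table::data.table(chrom = character(), pos = integer()))
  dt <- data.table::fread(path, header = grepl("chrom", first, fixed = TRUE))
  if (grepl("chrom", first, fixed = TRUE)) {
    stopifnot(all(c("chrom", "pos") %in% names(dt)))
    out <- dt[, list(chrom = as.character(chrom), pos = as.integer(pos))]
  } else if (ncol(dt) >= 3L && is.numeric(dt[[2L]]) && is.numeric(dt[[3L]])) {
    # BED: 0-based half-open; expand intervals to 1-based positions
    out <- dt[, list(pos = seq.int(.SD[[2L]] + 1L, .SD[[3L]])),
              by = seq_len(nrow(dt))][, seq_len := NULL]
    out[, chrom := rep(as.character(dt[[1L]]), dt[[3L]] - dt[[2L]])]
    out <- out[, c("chrom", "pos"), with = FALSE]
  } else if (ncol(dt) >= 2L) {
    out <- data.table::data.table(chrom = as.character(dt[[1L]]),
                                  pos = as.integer(dt[[2L]]))
  } else {
    stop("unrecognized site-list format: ", path)
  }
  bad <- which(is.na(out$pos))
  if (length(bad)) stop("malformed site record at line ", bad[1L], " of ", path)
  unique(out)
}

#' Find mononucleotide tracts in a reference
#'
#' Maximal runs of a single base of length at least `tract_min`,
#' reported 1-based half-open (`start` is the first base of the run,
#' `end` one past the last).
#'
#' @inheritParams load_resources
#' @return data.table with `chrom`, `start`, `end`, `base`.
#' @examples
#' find_homopolymers(c(chr1 = "ACGTAAAAC"))  # A-run at positions 5-8
#' @export
find_homopolymers <- function(reference, tract_min = 4L) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (inherits(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  stopifnot(is.character(reference), !is.null(names(reference)))
  out <- lapply(names(reference), function(chrom) {
    r <- rle(strsplit(toupper(reference[[chrom]]), "")[[1L]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= tract_min & r$values %in% c("A", "C", "G", "T")
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = chrom, start = starts[keep],
                           end = ends[keep] + 1L, base = r$values[keep])
  })
  out <- data.table::rbindlist(out[!vapply(out, is.null, logical(1L))])
  if (!nrow(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), base = character()))
  out[]
}
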