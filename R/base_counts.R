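#' Per-cell base-count table
#'
#' The atomic evidence unit of the caller: for every covered (locus,
#' cell) pair, the number of reads supporting each base.  Stored long
#' (one row per locus x barcode) with columns `chrom`, `pos`, `ref`,
#' `barcode`, `A`, `C`, `G`, `T`, `other`.  Cell-type labels, declared
#' empty-droplet barcodes and the mapping-quality cutoff used at
#' construction travel with the table as attributes.
#'
#' @param entries data.frame/data.table with the columns above.
#' @param cell_types Named character vector `barcode -> label`
#'   (`"cancer"` / `"noncancer"`), or a data.frame with columns
#'   `barcode` and `cell_type`.
#' @param droplets Character vector of declared empty-droplet barcodes
#'   (disjoint from cell barcodes).
#' @param min_mq Mapping-quality cutoff used when the table was built
#'   (`NA` when constructed from counts directly).
#' @return An object of class `base_count_table` (a `data.table`).
#' @export
base_count_table <- function(entries, cell_types, droplets = character(),
                             min_mq = NA_integer_) {
  dt <- data.table::as.data.table(entries)
  need <- c("chrom", "pos", "ref", "barcode", "A", "C", "G", "T", "other")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("base_count_table entries lack columns: ", paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            ref = as.character(ref), barcode = as.character(barcode))]
  for (b in c("A", "C", "G", "T", "other")) set(dt, j = b, value = as.integer(dt[[b]]))
  if (nrow(dt)) {
    if (any(dt$pos < 1L)) stop("positions must be >= 1")
    if (any(!dt$ref %in% c("A", "C", "G", "T")))
      stop("ref must be a single canonical base (A/C/G/T)")
    cnts <- as.matrix(dt[, c("A", "C", "G", "T", "other"), with = FALSE])
    if (any(cnts < 0L)) stop("counts must be non-negative")
  }
  ct <- normalize_cell_types(cell_types)
  droplets <- as.character(droplets)
  if (length(intersect(names(ct), droplets)))
    stop("droplet barcodes must be disjoint from cell barcodes")
  unknown <- setdiff(unique(dt$barcode), c(names(ct), droplets))
  if (length(unknown))
    stop("barcodes in entries missing from cell_types/droplets: ",
         paste(utils::head(unknown, 5L), collapse = ", "),
         if (length(unknown) > 5L) ", ..." else "")
  data.table::setkeyv(dt, c("chrom", "pos", "barcode"))
  data.table::setattr(dt, "cell_types", ct)
  data.table::setattr(dt, "droplets", droplets)
  data.table::setattr(dt, "min_mq", as.integer(min_mq))
  data.table::setattr(dt, "class",
                      c("base_count_table", class(data.table::data.table())))
  dt[]
}

normalize_cell_types <- function(cell_types) {
  if (is.data.frame(cell_types)) {
    ct <- stats::setNames(as.character(cell_types$cell_type),
                          as.character(cell_types$barcode))
  } else if (is.character(cell_types) && !is.null(names(cell_types))) {
    ct <- cell_types
  } else {
    stop("cell_types must be a named character vector or a ",
         "data.frame(barcode, cell_type)")
  }
  bad <- setdiff(unique(ct), c("cancer", "noncancer", "filtered"))
  if (length(bad))
    stop("unknown cell-type labels: ", paste(bad, collapse = ", "))
  ct
}

#' @export
print.base_count_table <- function(x, ...) {
  ct <- attr(x, "cell_types")
  cat(sprintf(
    "base_count_table: %d entries, %d loci, %d cells (%d cancer / %d noncancer)%s\n",
    nrow(x), data.table::uniqueN(x, by = c("chrom", "pos")),
    length(ct), sum(ct == "cancer"), sum(ct == "noncancer"),
    if (length(attr(x, "droplets")))
      sprintf(", %d droplets", length(attr(x, "droplets"))) else ""))
  NextMethod()
}

#' Cell-type labels of a count table
#' @param table A [base_count_table()].
#' @return Named character vector `barcode -> label`.
#' @export
cell_labels <- function(table) attr(table, "cell_types")

bc_depth <- function(dt) dt$A + dt$C + dt$G + dt$T + dt$other

base_count <- function(dt, base) {
  m <- as.matrix(dt[, c("A", "C", "G", "T"), with = FALSE])
  m[cbind(seq_len(nrow(dt)), match(base, c("A", "C", "G", "T")))]
}

#' Read / write the base-count TSV dialect
#'
#' Plain tab-separated text with header
#' `chrom pos ref barcode A C G T other`; round-trips a
#' [base_count_table()] exactly.
#'
#' @param table A [base_count_table()].
#' @param path File path.
#' @param cell_types,droplets,min_mq Passed to [base_count_table()] on
#'   reading.
#' @return `write_base_counts()` returns `path` invisibly;
#'   `read_base_counts()` returns a [base_count_table()].
#' @export
write_base_counts <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table)[
    , c("chrom", "pos", "ref", "barcode", "A", "C", "G", "T", "other"),
    with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_base_counts
#' @export
read_base_counts <- function(path, cell_types, droplets = character(),
                             min_mq = NA_integer_) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("chrom", "ref", "barcode")))
  base_count_table(dt, cell_types, droplets = droplets, min_mq = min_mq)
}

#' Aggregate cells into a pseudo-bulk
#'
#' Sums per-cell base counts over a named group of barcodes, emulating
#' a bulk sample of that cell population, and records for every locus
#' the number of member cells with at least one read.
#'
#' @param table A [base_count_table()].
#' @param group Character vector of member barcodes (must be a subset
#'   of the table's barcodes or declared droplets).
#' @param name Group name stored on the result.
#' @return A `pseudo_bulk` data.table with columns `chrom`, `pos`,
#'   `ref`, `A`, `C`, `G`, `T`, `other`, `depth`, `n_cells_covered`.
#' @export
aggregate_pseudobulk <- function(table, group, name = "group") {
  known <- c(names(attr(table, "cell_types")), attr(table, "droplets"))
  extra <- setdiff(group, known)
  if (length(extra))
    stop("group contains barcodes unknown to the table: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  if (!length(group))
    warning("empty group '", name, "': returning empty pseudo-bulk")
  sub <- data.table::as.data.table(table)[barcode %in% group]
  pb <- sub[, list(A = sum(A), C = sum(C), G = sum(G), T = sum(T),
                   other = sum(other),
                   n_cells_covered = sum((A + C + G + T + other) > 0L)),
            by = c("chrom", "pos", "ref")]
  pb[, depth := A + C + G + T + other]
  data.table::setkeyv(pb, c("chrom", "pos"))
  data.table::setattr(pb, "group_name", name)
  data.table::setattr(pb, "n_cells", length(group))
  data.table::setattr(pb, "class", c("pseudo_bulk", class(data.table::data.table())))
  pb[]
}

#' Pileup of a barcoded alignment file
#'
#' Builds a [base_count_table()] from an indexed BAM (or SAM, converted
#' on the fly) with per-read cell barcodes.  Only primary, non-duplicate
#' alignments with mapping quality at or above `min_mq` contribute, and
#' within a read only bases with base quality at or above `min_bq`.
#' Reads lacking a barcode tag, or whose barcode is neither a known
#' cell nor a declared droplet, are skipped and tallied in the
#' `skip_log` attribute of the result.
#'
#' @param path BAM file (indexed) or SAM file.
#' @param cell_types Named character vector `barcode -> label` or
#'   data.frame, as for [base_count_table()].
#' @param min_mq Minimum mapping quality (default 60, the maximum
#'   minimap2 emits, appropriate for high-quality long reads).
#' @param min_bq Minimum base quality (default 20, matching Q20
#'   preprocessed reads).
#' @param barcode_tag Candidate BAM tags holding the cell barcode,
#'   tried in order.
#' @param umi_tag Candidate BAM tags holding the UMI (carried through
#'   to the skip log only; deduplication is honoured via the duplicate
#'   flag).
#' @param droplets Declared empty-droplet barcodes.
#' @param reference Optional reference (FASTA path, `DNAStringSet`, or
#'   named character vector) used to set the `ref` column; when absent
#'   the majority base across all cells at each locus is used and a
#'   message is emitted.
#' @return A [base_count_table()] with a `skip_log` attribute.
#' @export
read_bam_pileup <- function(path, cell_types, min_mq = 60L, min_bq = 20L,
                            barcode_tag = c("CB", "XC"),
                            umi_tag = c("UB", "XM"),
                            droplets = character(), reference = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else {
    bai <- paste0(path, ".bai")
    bai2 <- sub("\\.bam$", ".bai", path)
    if (!file.exists(bai) && !file.exists(bai2))
      stop("missing BAM index for ", path,
           "; create one with Rsamtools::indexBam() or `samtools index`")
  }
  ct <- normalize_cell_types(cell_types)
  known <- c(names(ct), droplets)

  tags <- unique(c(barcode_tag, umi_tag))
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = tags)
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  n <- length(res$pos)
  skip <- c(no_barcode = 0L, unknown_barcode = 0L, low_mapq = 0L,
            flag_filtered = 0L)
  empty <- base_count_table(
    data.table::data.table(chrom = character(), pos = integer(),
                           ref = character(), barcode = character(),
                           A = integer(), C = integer(), G = integer(),
                           T = integer(), other = integer()),
    ct, droplets = droplets, min_mq = min_mq)
  if (n == 0L) {
    data.table::setattr(empty, "skip_log", skip)
    return(empty)
  }

  bc <- rep(NA_character_, n)
  for (tg in barcode_tag) {
    v <- res$tag[[tg]]
    if (!is.null(v)) bc[is.na(bc)] <- as.character(v[is.na(bc)])
  }
  flag <- res$flag
  bad_flag <- bitwAnd(flag, 0x4L) > 0L | bitwAnd(flag, 0x100L) > 0L |
    bitwAnd(flag, 0x800L) > 0L | bitwAnd(flag, 0x400L) > 0L
  low_mq <- !bad_flag & (is.na(res$mapq) | res$mapq < min_mq)
  no_bc <- !bad_flag & !low_mq & is.na(bc)
  unk <- !bad_flag & !low_mq & !no_bc & !(bc %in% known)
  skip["flag_filtered"] <- sum(bad_flag)
  skip["low_mapq"] <- sum(low_mq)
  skip["no_barcode"] <- sum(no_bc)
  skip["unknown_barcode"] <- sum(unk)
  use <- which(!(bad_flag | low_mq | no_bc | unk))
  if (!length(use)) {
    data.table::setattr(empty, "skip_log", skip)
    return(empty)
  }

  seqs <- as.character(res$seq[use])
  quals <- as.character(res$qual[use])
  parts <- vector("list", length(use))
  for (i in seq_along(use)) {
    r <- use[i]
    walked <- walk_cigar(res$cigar[r], res$pos[r], seqs[i], quals[i])
    if (is.null(walked)) next
    ok <- walked$bq >= min_bq
    if (!any(ok)) next
    parts[[i]] <- data.table::data.table(
      chrom = as.character(res$rname[r]), pos = walked$pos[ok],
      base = walked$base[ok], barcode = bc[r])
  }
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  if (!length(parts)) {
    data.table::setattr(empty, "skip_log", skip)
    return(empty)
  }
  long <- data.table::rbindlist(parts)
  long[, base := ifelse(base %in% c("A", "C", "G", "T"), base, "other")]
  wide <- data.table::dcast(
    long[, list(n = .N), by = c("chrom", "pos", "barcode", "base")],
    chrom + pos + barcode ~ base, value.var = "n", fill = 0L)
  for (b in c("A", "C", "G", "T", "other"))
    if (!b %in% names(wide)) wide[, (b) := 0L]

  refs <- lookup_reference(reference, wide)
  if (is.null(refs)) {
    message("no reference supplied: using the majority base at each ",
            "locus as `ref`")
    loc <- wide[, list(A = sum(A), C = sum(C), G = sum(G), T = sum(T)),
                by = c("chrom", "pos")]
    m <- as.matrix(loc[, c("A", "C", "G", "T"), with = FALSE])
    loc[, ref := c("A", "C", "G", "T")[max.col(m, ties.method = "first")]]
    wide <- merge(wide, loc[, c("chrom", "pos", "ref"), with = FALSE],
                  by = c("chrom", "pos"))
  } else {
    wide[, ref := refs]
  }
  out <- base_count_table(wide, ct, droplets = droplets, min_mq = min_mq)
  data.table::setattr(out, "skip_log", skip)
  out
}

# returns per-row reference bases for the (chrom, pos) of `wide`,
# or NULL when no reference is available
lookup_reference <- function(reference, wide) {
  if (is.null(reference)) return(NULL)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (!is.character(reference) || is.null(names(reference)))
    stop("reference must be a FASTA path, DNAStringSet, or named ",
         "character vector")
  miss <- setdiff(unique(wide$chrom), names(reference))
  if (length(miss))
    stop("reference lacks sequences: ", paste(miss, collapse = ", "))
  toupper(substring(reference[wide$chrom], wide$pos, wide$pos))
}

# walk one CIGAR string; returns reference positions, bases and base
# qualities of aligned (M/=/X) bases
walk_cigar <- function(cigar, start, seq, qual) {
  if (is.na(cigar) || is.na(start)) return(NULL)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops)) return(NULL)
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  type <- substring(ops, nchar(ops))
  qpos <- 1L; rpos <- start
  pos <- integer(0); idx <- integer(0)
  for (i in seq_along(ops)) {
    L <- lens[i]
    switch(type[i],
           "M" = , "=" = , "X" = {
             pos <- c(pos, rpos:(rpos + L - 1L))
             idx <- c(idx, qpos:(qpos + L - 1L))
             qpos <- qpos + L; rpos <- rpos + L
           },
           "I" = , "S" = { qpos <- qpos + L },
           "D" = , "N" = { rpos <- rpos + L },
           "H" = , "P" = NULL)
  }
  if (!length(pos)) return(NULL)
  bases <- substring(seq, idx, idx)
  bq <- as.integer(charToRaw(qual))[idx] - 33L
  list(pos = pos, base = toupper(bases), bq = bq)
}

#' Long-read panel of normals
#'
#' A locus enters the panel when its non-reference read count is
#' significantly above the background error rate (one-sided
#' beta-binomial test, strict `< alpha_level`) in at least one of the
#' supplied normal-sample pseudo-bulks.  Matched samples of the patient
#' under analysis must be excluded by the caller (leave-one-patient-out).
#'
#' @param normal_pileups List of `pseudo_bulk` tables from normal
#'   samples.
#' @param params Background-error [beta_params()].
#' @param alpha_level Significance level (strict) for panel membership.
#' @return data.table of panel loci (`chrom`, `pos`).
#' @export
build_lr_pon <- function(normal_pileups, params, alpha_level = 0.05) {
  if (!length(normal_pileups)) {
    warning("no normal samples supplied: returning an empty panel")
    return(data.table::data.table(chrom = character(), pos = integer()))
  }
  hits <- lapply(normal_pileups, function(pb) {
    pb <- data.table::as.data.table(pb)
    if (!nrow(pb)) return(NULL)
    nonref <- bc_depth(pb) - base_count(pb, pb$ref)
    sig <- is_significant(nonref, bc_depth(pb), params, alpha_level)
    pb[sig, c("chrom", "pos"), with = FALSE]
  })
  out <- unique(data.table::rbindlist(hits[!vapply(hits, is.null, logical(1L))]))
  if (!nrow(out)) return(data.table::data.table(chrom = character(), pos = integer()))
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

#' Variant allele fraction in empty droplets
#'
#' Per-droplet VAF at the supplied loci (typically called mitochondrial
#' variants), used to quantify ambient cancer RNA.  Droplets with no
#' coverage at a locus are omitted.
#'
#' @param table A [base_count_table()] whose `droplets` attribute (or
#'   `droplet_barcodes`) names the empty droplets.
#' @param droplet_barcodes Character vector of droplet barcodes.
#' @param loci data.frame with columns `chrom`, `pos`, `alt`.
#' @return data.table with one row per (droplet, locus) with coverage:
#'   `barcode`, `chrom`, `pos`, `alt`, `alt_reads`, `depth`, `vaf`.
#' @export
empty_droplet_vaf <- function(table, droplet_barcodes = attr(table, "droplets"),
                              loci) {
  loci <- data.table::as.data.table(loci)
  stopifnot(all(c("chrom", "pos", "alt") %in% names(loci)))
  if (length(intersect(droplet_barcodes, names(attr(table, "cell_types")))))
    stop("droplet barcodes must be disjoint from cell barcodes")
  sub <- data.table::as.data.table(table)[barcode %in% droplet_barcodes]
  sub <- merge(sub, loci[, c("chrom", "pos", "alt"), with = FALSE],
               by = c("chrom", "pos"))
  if (!nrow(sub))
    return(data.table::data.table(barcode = character(), chrom = character(),
                                  pos = integer(), alt = character(),
                                  alt_reads = integer(), depth = integer(),
                                  vaf = numeric()))
  sub[, depth := bc_depth(sub)]
  sub[, alt_reads := base_count(sub, alt)]
  sub <- sub[depth >= 1L]
  sub[, vaf := alt_reads / depth]
  sub[, c("barcode", "chrom", "pos", "alt", "alt_reads", "depth", "vaf"),
      with = FALSE]
}
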