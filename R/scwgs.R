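#' Pooled scWGS clone counts
#'
#' Per-locus base counts for the pooled aneuploid ("cancer") and
#' pooled diploid ("noncancer") single-cell whole-genome-sequencing
#' clones.  Subclones are pooled because per-subclone coverage is low.
#'
#' @param counts data.frame with columns `chrom`, `pos`, `ref`,
#'   `pool` (`"aneuploid"` / `"diploid"`), `A`, `C`, `G`, `T`, `other`.
#' @return A `clone_counts` data.table.
#' @export
clone_counts <- function(counts) {
  dt <- data.table::as.data.table(counts)
  need <- c("chrom", "pos", "ref", "pool", "A", "C", "G", "T", "other")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("clone_counts lack columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(dt$pool), c("aneuploid", "diploid"))
  if (length(bad)) stop("unknown pools: ", paste(bad, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, pos := as.integer(pos)]
  data.table::setkeyv(dt, c("chrom", "pos", "pool"))
  data.table::setattr(dt, "class",
                      c("clone_counts", class(data.table::data.table())))
  dt[]
}

#' @rdname clone_counts
#' @param path TSV path (same columns, tab-separated, with header).
#' @export
read_clone_counts <- function(path) {
  clone_counts(data.table::fread(path, sep = "\t"))
}

#' @rdname clone_counts
#' @param counts A `clone_counts` table.
#' @export
write_clone_counts <- function(counts, path) {
  data.table::fwrite(data.table::as.data.table(counts), path, sep = "\t")
  invisible(path)
}

pool_alt <- function(cc, loci, which_pool) {
  sub <- data.table::as.data.table(cc)[pool == which_pool]
  m <- merge(loci[, c("chrom", "pos", "alt"), with = FALSE], sub,
             by = c("chrom", "pos"), all.x = TRUE)
  m <- m[match(paste(loci$chrom, loci$pos), paste(m$chrom, m$pos))]
  for (b in c("A", "C", "G", "T", "other"))
    data.table::set(m, which(is.na(m[[b]])), b, 0L)
  list(alt = base_count(m, m$alt), depth = bc_depth(m))
}

#' Classify scRNA-seq calls against scWGS clone counts
#'
#' Each locus called in scRNA-seq is tested in the pooled aneuploid
#' and pooled diploid scWGS clones with the one-sided beta-binomial
#' test (strict `< scwgs_level`).  A locus is eligible when it has at
#' least one mutated (alternative) read or at least `scwgs_min_depth`
#' (17) reads of total coverage; ineligible loci are labelled
#' `"ineligible"`.  Eligible loci are `"somatic"` when significant in
#' the aneuploid pool only, `"germline"` when significant in the
#' diploid pool, and `"uncalled"` when significant in neither.
#'
#' @param loci data.frame of called loci (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param counts A [clone_counts()] table.
#' @param params Background-error [beta_params()] for the scWGS pools.
#' @param thresholds A [calling_thresholds()] list.
#' @return data.table `loci` plus per-pool counts, p-values, and
#'   `label`.
#' @export
classify_support <- function(loci, counts, params,
                             thresholds = calling_thresholds()) {
  loci <- data.table::as.data.table(loci)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  out <- data.table::copy(loci)
  if (!nrow(out)) {
    out[, label := character(0)]
    return(out[])
  }
  an <- pool_alt(counts, loci, "aneuploid")
  di <- pool_alt(counts, loci, "diploid")
  out[, `:=`(aneuploid_alt = an$alt, aneuploid_depth = an$depth,
             diploid_alt = di$alt, diploid_depth = di$depth)]
  mut <- out$aneuploid_alt + out$diploid_alt
  depth <- out$aneuploid_depth + out$diploid_depth
  eligible <- mut >= 1L | depth >= thresholds$scwgs_min_depth
  p_an <- bb_tail(out$aneuploid_alt, out$aneuploid_depth, params)
  p_di <- bb_tail(out$diploid_alt, out$diploid_depth, params)
  sig_an <- p_an < thresholds$scwgs_level
  sig_di <- p_di < thresholds$scwgs_level
  out[, `:=`(p_aneuploid = p_an, p_diploid = p_di)]
  out[, label := ifelse(!eligible, "ineligible",
                        ifelse(sig_di, "germline",
                               ifelse(sig_an, "somatic", "uncalled")))]
  out[]
}

#' De novo scWGS somatic truth set
#'
#' Builds an independent somatic truth set directly from the scWGS
#' clone counts: sites need at least `denovo_min_reads` (5) reads in
#' both scRNA pseudo-bulks and in both scWGS pools, and (when per-cell
#' aneuploid counts are available) at least `denovo_min_alt_reads` (3)
#' alternative reads in at least `denovo_min_alt_cells` (2) aneuploid
#' cells; with pooled-only input this sub-filter is skipped with a
#' message.  An eligible site enters the truth set when the
#' beta-binomial test gives `p < denovo_aneuploid_level` (0.001) in
#' the aneuploid pool and `p > denovo_diploid_level` (0.05) in the
#' diploid pool.
#'
#' @param counts A [clone_counts()] table.
#' @param rna_cancer_pb,rna_noncancer_pb `pseudo_bulk` tables of the
#'   scRNA cancer / non-cancer populations.
#' @param params Background-error [beta_params()] for scWGS.
#' @param cell_alt_counts Optional data.frame of per-aneuploid-cell
#'   counts (`chrom`, `pos`, `cell`, `alt_reads`).
#' @param thresholds A [calling_thresholds()] list.
#' @return data.table of eligible sites with p-values and a logical
#'   `somatic` column (the truth set is `result[somatic == TRUE]`).
#' @export
call_scwgs_denovo <- function(counts, rna_cancer_pb, rna_noncancer_pb,
                              params, cell_alt_counts = NULL,
                              thresholds = calling_thresholds()) {
  th <- thresholds
  cc <- data.table::as.data.table(counts)
  sites <- unique(cc[, c("chrom", "pos", "ref"), with = FALSE])
  # the alternative allele at each site: most frequent non-reference
  # base in the aneuploid pool (the pool where a somatic signal lives)
  an <- cc[pool == "aneuploid"]
  an <- an[match(paste(sites$chrom, sites$pos), paste(an$chrom, an$pos))]
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(an[, bases, with = FALSE])
  cnt[is.na(cnt)] <- 0L
  cnt[cbind(seq_len(nrow(sites)), match(sites$ref, bases))] <- -1L
  sites[, alt := bases[max.col(cnt, ties.method = "first")]]

  anp <- pool_alt(cc, sites, "aneuploid")
  dip <- pool_alt(cc, sites, "diploid")
  rna_c <- merge(sites[, c("chrom", "pos"), with = FALSE],
                 data.table::as.data.table(rna_cancer_pb),
                 by = c("chrom", "pos"), all.x = TRUE)
  rna_n <- merge(sites[, c("chrom", "pos"), with = FALSE],
                 data.table::as.data.table(rna_noncancer_pb),
                 by = c("chrom", "pos"), all.x = TRUE)
  dc <- rna_c$depth[match(paste(sites$chrom, sites$pos),
                          paste(rna_c$chrom, rna_c$pos))]
  dn <- rna_n$depth[match(paste(sites$chrom, sites$pos),
                          paste(rna_n$chrom, rna_n$pos))]
  dc[is.na(dc)] <- 0L; dn[is.na(dn)] <- 0L

  eligible <- dc >= th$denovo_min_reads & dn >= th$denovo_min_reads &
    anp$depth >= th$denovo_min_reads & dip$depth >= th$denovo_min_reads
  if (!is.null(cell_alt_counts)) {
    ca <- data.table::as.data.table(cell_alt_counts)
    supp <- ca[alt_reads >= th$denovo_min_alt_reads,
               list(n_cells = data.table::uniqueN(cell)),
               by = c("chrom", "pos")]
    ns <- supp$n_cells[match(paste(sites$chrom, sites$pos),
                             paste(supp$chrom, supp$pos))]
    ns[is.na(ns)] <- 0L
    eligible <- eligible & ns >= th$denovo_min_alt_cells
  } else {
    message("no per-cell aneuploid counts supplied: skipping the ",
            "mutated-reads-in-multiple-cells sub-filter")
  }
  out <- sites[eligible]
  if (!nrow(out)) {
    out[, `:=`(p_aneuploid = numeric(0), p_diploid = numeric(0),
               somatic = logical(0))]
    return(out[])
  }
  keep <- which(eligible)
  p_an <- bb_tail(anp$alt[keep], anp$depth[keep], params)
  p_di <- bb_tail(dip$alt[keep], dip$depth[keep], params)
  out[, `:=`(p_aneuploid = p_an, p_diploid = p_di)]
  out[, somatic := p_an < th$denovo_aneuploid_level &
        p_di > th$denovo_diploid_level]
  out[]
}

#' Sensitivity, precision and F1 of a call set
#'
#' Compared on locus identity against a truth set, optionally
#' restricted to truth-eligible loci.  With no calls, precision is
#' undefined and reported as 0 with `no_calls = TRUE`.
#'
#' @param calls,truth data.frames with `chrom` and `pos` (extra
#'   columns ignored), or character vectors of `chrom:pos` keys.
#' @param eligible Optional set (same forms) restricting the
#'   evaluation universe.
#' @return list with `tp`, `fp`, `fn`, `precision`, `sensitivity`,
#'   `f1`, `no_calls`.
#' @export
performance <- function(calls, truth, eligible = NULL) {
  as_key <- function(x) {
    if (is.character(x)) return(unique(x))
    x <- data.table::as.data.table(x)
    if (!nrow(x)) return(character(0))
    unique(paste(x$chrom, x$pos, sep = ":"))
  }
  k_calls <- as_key(calls); k_truth <- as_key(truth)
  if (!is.null(eligible)) {
    k_el <- as_key(eligible)
    k_calls <- intersect(k_calls, k_el)
    k_truth <- intersect(k_truth, k_el)
  }
  tp <- length(intersect(k_calls, k_truth))
  fp <- length(setdiff(k_calls, k_truth))
  fn <- length(setdiff(k_truth, k_calls))
  no_calls <- (tp + fp) == 0L
  precision <- if (no_calls) 0 else tp / (tp + fp)
  sensitivity <- if ((tp + fn) == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision,
       sensitivity = sensitivity, f1 = f1, no_calls = no_calls)
}
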