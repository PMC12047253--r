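#' Calling thresholds
#'
#' Every numeric threshold of the caller in one place, with the
#' documented defaults.  All significance comparisons are strict
#' (`p < level`); all count thresholds are inclusive ("at least").
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of thresholds.
#' @details
#' Nuclear SNV battery: `min_depth` (5; pseudo-bulk coverage in both
#' cancer and non-cancer), `min_alt_cells` (2) each with
#' `min_alt_reads_per_cell` (3), `noise_level` (0.001, cancer noise
#' test), `other_noise_level` (0.05, residual non-reference alleles),
#' `homopolymer_min_len` (4) and `homopolymer_flank` (4 bp),
#' `germline_level` (0.05, non-cancer test — stricter at filtering
#' germline than the 0.001 a matched-normal-free caller would
#' otherwise use), `gnomad_max_af` (0.01), `min_distance` (10000 bp).
#'
#' High-confidence cancer variants: `hccv_min_depth` (20),
#' `hccv_max_vaf_noncancer` (0.2), `hccv_min_delta_mcf` (0.4);
#' reannotation: `reannot_min_covered` (3), `reannot_min_fraction`
#' (0.25, inclusive).
#'
#' Mitochondrial: `mt_min_depth` (100), `mt_min_delta_mcf` (0.35,
#' inclusive), `mt_min_vaf_cancer` (0.1, inclusive),
#' `mt_genotype_vaf` (0.3, per-cell, strict >).
#'
#' Fusions: `fusion_min_mcf_cancer` (0.05, strict >),
#' `fusion_max_mcf_noncancer` (0.01, strict <).
#'
#' Genotyping / matrix: `genotype_level` (0.01), `matrix_min_cells_snv`
#' (5), `matrix_min_cells_fusion` (3), `matrix_min_variants_cell` (3).
#'
#' scWGS: `scwgs_level` (0.01), `scwgs_min_depth` (17),
#' `denovo_aneuploid_level` (0.001), `denovo_diploid_level` (0.05),
#' `denovo_min_reads` (5), `denovo_min_alt_cells` (2),
#' `denovo_min_alt_reads` (3).
#' @export
calling_thresholds <- function(...) {
  defaults <- list(
    min_depth = 5L, min_alt_cells = 2L, min_alt_reads_per_cell = 3L,
    noise_level = 0.001, other_noise_level = 0.05,
    homopolymer_min_len = 4L, homopolymer_flank = 4L,
    germline_level = 0.05, gnomad_max_af = 0.01, min_distance = 10000L,
    hccv_min_depth = 20L, hccv_max_vaf_noncancer = 0.2,
    hccv_min_delta_mcf = 0.4, reannot_min_covered = 3L,
    reannot_min_fraction = 0.25,
    mt_min_depth = 100L, mt_min_delta_mcf = 0.35, mt_min_vaf_cancer = 0.1,
    mt_genotype_vaf = 0.3,
    fusion_min_mcf_cancer = 0.05, fusion_max_mcf_noncancer = 0.01,
    genotype_level = 0.01, matrix_min_cells_snv = 5L,
    matrix_min_cells_fusion = 3L, matrix_min_variants_cell = 3L,
    scwgs_level = 0.01, scwgs_min_depth = 17L,
    denovo_aneuploid_level = 0.001, denovo_diploid_level = 0.05,
    denovo_min_reads = 5L, denovo_min_alt_cells = 2L,
    denovo_min_alt_reads = 3L,
    mt_chroms = c("chrM", "MT", "chrMT"))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown thresholds: ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, over)
}

#' Detect candidate loci from the cancer pseudo-bulk
#'
#' A (locus, alt) pair is a candidate when the aggregated cancer cells
#' show at least one read of a non-reference allele and at least
#' `min_depth` reads of coverage.  The alternative allele is the most
#' frequent non-reference base (ties broken in base order A < C < G <
#' T); multi-allelic loci collapse to this single allele.
#'
#' @param cancer_pb A `pseudo_bulk` of the (re)annotated cancer cells.
#' @param min_depth Minimum aggregated cancer coverage (inclusive).
#' @param min_alt Minimum aggregated alternative reads (inclusive).
#' @return data.table with `chrom`, `pos`, `ref`, `alt`, `cancer_alt`,
#'   `cancer_depth`, `cancer_nonref`.
#' @export
detect_candidates <- function(cancer_pb, min_depth = 5L, min_alt = 1L) {
  pb <- data.table::as.data.table(cancer_pb)
  if (!nrow(pb))
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  cancer_alt = integer(),
                                  cancer_depth = integer(),
                                  cancer_nonref = integer()))
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pb[, bases, with = FALSE])
  cnt[cbind(seq_len(nrow(pb)), match(pb$ref, bases))] <- -1L  # mask ref
  alt_idx <- max.col(cnt, ties.method = "first")  # first = base order
  pb[, alt := bases[alt_idx]]
  pb[, cancer_alt := cnt[cbind(.I, alt_idx)]]
  pb[, cancer_nonref := depth - base_count(pb, ref) ]
  out <- pb[cancer_alt >= min_alt & depth >= min_depth,
            list(chrom, pos, ref, alt, cancer_alt,
                 cancer_depth = depth, cancer_nonref)]
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

#' Assemble fully-annotated variant records
#'
#' Builds candidate records from the cancer pseudo-bulk and annotates
#' each with non-cancer counts, VAFs, mutated-cell fractions (MCF) in
#' both populations, their difference (delta MCF), and the number of
#' cancer cells with at least `min_alt_reads_per_cell` alternative
#' reads.  MCFs are computed with the single-cell genotyping rules
#' (beta-binomial for nuclear loci, per-cell VAF for mitochondrial).
#'
#' @param table A [base_count_table()].
#' @param labels Named character vector `barcode -> label`; cells
#'   labelled `"filtered"` are excluded from both pseudo-bulks.
#' @param params Background-error [beta_params()] (primary set).
#' @param thresholds A [calling_thresholds()] list.
#' @return data.table of variant records, one per candidate locus.
#' @export
build_variant_records <- function(table, labels = cell_labels(table),
                                  params = default_beta_params("primary"),
                                  thresholds = calling_thresholds()) {
  labels <- normalize_cell_types(labels)
  cancer <- names(labels)[labels == "cancer"]
  noncancer <- names(labels)[labels == "noncancer"]
  cancer_pb <- aggregate_pseudobulk(table, cancer, "cancer")
  noncancer_pb <- aggregate_pseudobulk(table, noncancer, "noncancer")
  cand <- detect_candidates(cancer_pb, min_depth = thresholds$min_depth)
  if (!nrow(cand)) return(empty_records())

  nc <- data.table::as.data.table(noncancer_pb)
  if (nrow(nc)) {
    nc2 <- cand[, c("chrom", "pos", "alt"), with = FALSE]
    nc <- merge(nc2, nc, by = c("chrom", "pos"), all.x = TRUE)
    nc[is.na(depth), `:=`(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L,
                          depth = 0L)]
    cand[, noncancer_depth := nc$depth]
    cand[, noncancer_alt := base_count(nc, nc$alt)]
  } else {
    cand[, `:=`(noncancer_depth = 0L, noncancer_alt = 0L)]
  }
  cand[, vaf_cancer := ifelse(cancer_depth > 0, cancer_alt / cancer_depth, 0)]
  cand[, vaf_noncancer := ifelse(noncancer_depth > 0,
                                 noncancer_alt / noncancer_depth, 0)]

  # cells with >= min_alt_reads_per_cell alternative reads (cancer)
  sub <- data.table::as.data.table(table)[barcode %in% cancer]
  sub <- merge(cand[, c("chrom", "pos", "alt"), with = FALSE], sub,
               by = c("chrom", "pos"))
  if (nrow(sub)) {
    sub[, alt_reads := base_count(sub, alt)]
    n3 <- sub[alt_reads >= thresholds$min_alt_reads_per_cell,
              list(n = .N), by = c("chrom", "pos")]
    cand <- merge(cand, n3, by = c("chrom", "pos"), all.x = TRUE)
    cand[is.na(n), n := 0L]
    data.table::setnames(cand, "n", "n_cancer_cells_alt3")
  } else {
    cand[, n_cancer_cells_alt3 := 0L]
  }

  mcf_c <- compute_mcf(table, cand, cancer, params,
                       level = thresholds$genotype_level,
                       mt_vaf_threshold = thresholds$mt_genotype_vaf,
                       mt_chroms = thresholds$mt_chroms)
  mcf_n <- compute_mcf(table, cand, noncancer, params,
                       level = thresholds$genotype_level,
                       mt_vaf_threshold = thresholds$mt_genotype_vaf,
                       mt_chroms = thresholds$mt_chroms)
  cand[, mcf_cancer := mcf_c$mcf]
  cand[, mcf_noncancer := mcf_n$mcf]
  cand[, delta_mcf := mcf_cancer - mcf_noncancer]
  data.table::setkeyv(cand, c("chrom", "pos"))
  cand[]
}

empty_records <- function() {
  data.table::data.table(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), cancer_alt = integer(), cancer_depth = integer(),
    cancer_nonref = integer(), noncancer_depth = integer(),
    noncancer_alt = integer(), vaf_cancer = numeric(),
    vaf_noncancer = numeric(), n_cancer_cells_alt3 = integer(),
    mcf_cancer = numeric(), mcf_noncancer = numeric(),
    delta_mcf = numeric())
}

# ---- the ten per-record filters (TRUE = pass) -------------------------

#' Nuclear SNV filters
#'
#' Vectorized pass/fail decisions of the ordered filter battery, each
#' returning a logical vector aligned with the rows of `records` (TRUE
#' = pass).  See [calling_thresholds()] for the thresholds and
#' [call_somatic_snvs()] for the assembled battery.
#'
#' @param records A variant-record data.table from
#'   [build_variant_records()].
#' @param thresholds A [calling_thresholds()] list.
#' @return Logical vector, TRUE where the record passes.
#' @name snv_filters
NULL

#' @describeIn snv_filters Step 1 — fail loci with less than
#'   `min_depth` aggregated reads in cancer or in non-cancer cells.
#' @export
filter_coverage <- function(records, thresholds = calling_thresholds()) {
  records$cancer_depth >= thresholds$min_depth &
    records$noncancer_depth >= thresholds$min_depth
}

#' @describeIn snv_filters Step 2 — require at least `min_alt_cells`
#'   cancer cells each carrying at least `min_alt_reads_per_cell`
#'   alternative reads (uses the precomputed `n_cancer_cells_alt3`).
#' @export
filter_alt_support <- function(records, thresholds = calling_thresholds()) {
  records$n_cancer_cells_alt3 >= thresholds$min_alt_cells
}

#' @describeIn snv_filters Step 3 — the cancer-cell alternative counts
#'   must be significantly above background error (strict
#'   `< noise_level`), else the locus is noise.
#' @param params1 Primary background-error [beta_params()].
#' @export
filter_noise_cancer <- function(records, params1,
                                thresholds = calling_thresholds()) {
  if (!nrow(records)) return(logical(0))
  is_significant(records$cancer_alt, records$cancer_depth, params1,
                 thresholds$noise_level)
}

#' @describeIn snv_filters Step 4 — ignoring reads that carry the
#'   candidate allele, the remaining non-reference counts must NOT be
#'   significantly above background (strict `< other_noise_level`
#'   fails).
#' @param params2 Other-allele background-error [beta_params()].
#' @export
filter_other_allele_noise <- function(records, params2,
                                      thresholds = calling_thresholds()) {
  if (!nrow(records)) return(logical(0))
  k <- records$cancer_nonref - records$cancer_alt
  n <- records$cancer_depth - records$cancer_alt
  ok <- n > 0L
  out <- rep(TRUE, nrow(records))  # n' = 0 is vacuously clean
  out[ok] <- !is_significant(k[ok], n[ok], params2,
                             thresholds$other_noise_level)
  out
}

#' @describeIn snv_filters Step 5 — fail loci inside, or within
#'   `homopolymer_flank` bp of either end of, a mononucleotide tract of
#'   length at least `homopolymer_min_len`.
#' @param resources An [annotation_resources()] bundle.
#' @export
filter_homopolymer <- function(records, resources,
                               thresholds = calling_thresholds()) {
  if (!nrow(records)) return(logical(0))
  hp <- resources$homopolymers
  hp <- hp[(hp$end - hp$start) >= thresholds$homopolymer_min_len, ]
  if (!nrow(hp)) return(rep(TRUE, nrow(records)))
  fl <- thresholds$homopolymer_flank
  bad <- vapply(seq_len(nrow(records)), function(i) {
    h <- hp[hp$chrom == records$chrom[i], ]
    any(records$pos[i] >= h$start - fl & records$pos[i] <= h$end - 1L + fl)
  }, logical(1L))
  !bad
}

#' @describeIn snv_filters Step 6 — fail loci present in the
#'   RNA-editing site list.
#' @export
filter_editing <- function(records, resources) {
  if (!nrow(records)) return(logical(0))
  !site_member(records, resources$editing)
}

#' @describeIn snv_filters Step 7 — fail loci present in either the
#'   short-read or the long-read panel of normals (`use = "lr"`
#'   restricts to the long-read panel, as for mitochondrial loci).
#' @param use `"both"` or `"lr"`.
#' @export
filter_pon <- function(records, resources, use = c("both", "lr")) {
  use <- match.arg(use)
  if (!nrow(records)) return(logical(0))
  hit <- site_member(records, resources$pon_lr)
  if (use == "both") hit <- hit | site_member(records, resources$pon_sr)
  !hit
}

#' @describeIn snv_filters Step 8 — fail loci whose non-cancer
#'   alternative counts are significantly above background (strict
#'   `< germline_level`): likely germline polymorphisms.
#' @export
filter_germline <- function(records, params1,
                            thresholds = calling_thresholds()) {
  if (!nrow(records)) return(logical(0))
  !is_significant(records$noncancer_alt, records$noncancer_depth, params1,
                  thresholds$germline_level)
}

#' @describeIn snv_filters Step 9 — fail loci whose alternative allele
#'   reaches a population frequency of at least `gnomad_max_af`.
#' @export
filter_gnomad <- function(records, resources,
                          thresholds = calling_thresholds()) {
  if (!nrow(records)) return(logical(0))
  g <- resources$gnomad
  if (!nrow(g)) return(rep(TRUE, nrow(records)))
  key <- paste(records$chrom, records$pos, records$alt)
  af <- g$af[match(key, paste(g$chrom, g$pos, g$alt))]
  is.na(af) | af < thresholds$gnomad_max_af
}

site_member <- function(records, sites) {
  if (!nrow(sites)) return(rep(FALSE, nrow(records)))
  paste(records$chrom, records$pos) %in% paste(sites$chrom, sites$pos)
}

#' @describeIn snv_filters Step 10 — among the records given (those
#'   passing steps 1-9), remove every record with another record on the
#'   same chromosome within `min_distance` bp; both members of a close
#'   pair are removed.  Symmetric and order-independent.
#' @export
filter_distance <- function(records, thresholds = calling_thresholds()) {
  n <- nrow(records)
  if (!n) return(logical(0))
  keep <- rep(TRUE, n)
  ord <- order(records$chrom, records$pos)
  chrom <- records$chrom[ord]; pos <- records$pos[ord]
  if (n > 1L) {
    close_next <- chrom[-n] == chrom[-1L] &
      (pos[-1L] - pos[-n]) <= thresholds$min_distance
    bad <- c(close_next, FALSE) | c(FALSE, close_next)
    keep[ord] <- !bad
  }
  keep
}

filter_steps_nuclear <- c("coverage", "alt_support", "noise_cancer",
                          "other_noise", "homopolymer", "editing", "pon",
                          "germline", "gnomad", "distance")

#' Call somatic nuclear SNVs
#'
#' Runs the full candidate-detection and 10-step filter battery on the
#' nuclear genome (mitochondrial contigs are excluded here and handled
#' by [call_somatic_mtsnvs()]).  Cell-type labels should be the
#' reannotated ones (see [reannotate_cells()]).  Every candidate
#' receives a complete per-filter ledger; the funnel records, for each
#' step in order, how many candidates entered, passed, and failed, so
#' that `pass(i) = pass(i-1) - fail(i)` at every step.
#'
#' @param table A [base_count_table()].
#' @param cell_types Named character vector `barcode -> label`
#'   (reannotated; `"filtered"` cells are excluded).
#' @param resources An [annotation_resources()] bundle.
#' @param params1,params2 Primary and other-allele [beta_params()].
#' @param thresholds A [calling_thresholds()] list.
#' @param records Optional precomputed [build_variant_records()] table
#'   (nuclear loci only); when supplied, `table`/`cell_types` are not
#'   touched for record construction.
#' @return An object of class `call_set`: list with `records` (all
#'   candidates + ledger columns `pass_*`), `somatic` (records passing
#'   all steps), and `funnel`.
#' @export
call_somatic_snvs <- function(table, cell_types = cell_labels(table),
                              resources = annotation_resources(),
                              params1 = default_beta_params("primary"),
                              params2 = default_beta_params("other"),
                              thresholds = calling_thresholds(),
                              records = NULL) {
  if (is.null(records)) {
    records <- build_variant_records(table, cell_types, params1, thresholds)
    records <- records[!chrom %in% thresholds$mt_chroms]
  }
  records <- data.table::copy(data.table::as.data.table(records))
  ledger <- list(
    coverage = filter_coverage(records, thresholds),
    alt_support = filter_alt_support(records, thresholds),
    noise_cancer = filter_noise_cancer(records, params1, thresholds),
    other_noise = filter_other_allele_noise(records, params2, thresholds),
    homopolymer = filter_homopolymer(records, resources, thresholds),
    editing = filter_editing(records, resources),
    pon = filter_pon(records, resources, "both"),
    germline = filter_germline(records, params1, thresholds),
    gnomad = filter_gnomad(records, resources, thresholds))
  for (nm in names(ledger)) records[, (paste0("pass_", nm)) := ledger[[nm]]]
  alive <- if (nrow(records)) Reduce(`&`, ledger) else logical(0)
  # distance filter acts on the step-1-9 survivors only
  dist_pass <- rep(NA, nrow(records))
  if (any(alive))
    dist_pass[alive] <- filter_distance(records[alive], thresholds)
  records[, pass_distance := dist_pass]
  call_set(records, steps = filter_steps_nuclear)
}

call_set <- function(records, steps) {
  n_in <- nrow(records)
  funnel <- data.table::data.table(step = steps, n_in = NA_integer_,
                                   n_pass = NA_integer_, n_fail = NA_integer_)
  surv <- rep(TRUE, n_in)
  for (i in seq_along(steps)) {
    p <- records[[paste0("pass_", steps[i])]]
    p[is.na(p)] <- FALSE
    data.table::set(funnel, i, "n_in", sum(surv))
    fail_here <- surv & !p
    data.table::set(funnel, i, "n_fail", sum(fail_here))
    surv <- surv & p
    data.table::set(funnel, i, "n_pass", sum(surv))
  }
  structure(list(records = records[], somatic = records[surv],
                 funnel = funnel),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("call_set: %d candidates -> %d somatic calls\n",
              nrow(x$records), nrow(x$somatic)))
  print(x$funnel)
  invisible(x)
}

#' Write calls as VCF and the funnel as TSV
#'
#' VCF 4.2 text output: the FILTER column carries `PASS` or the first
#' failing step; INFO carries the per-group depths, VAFs, MCFs and
#' delta MCF (and `MT=1` for mitochondrial calls).
#'
#' @param callset A `call_set`.
#' @param path Output file.
#' @param mt Mark records as mitochondrial in INFO.
#' @param all_candidates Write every candidate (default) or only
#'   passing calls.
#' @return `path`, invisibly.
#' @export
write_call_vcf <- function(callset, path, mt = FALSE, all_candidates = TRUE) {
  rec <- if (all_candidates) callset$records else callset$somatic
  steps <- sub("^pass_", "", grep("^pass_", names(rec), value = TRUE))
  filt <- rep("PASS", nrow(rec))
  for (i in rev(seq_along(steps))) {
    p <- rec[[paste0("pass_", steps[i])]]
    filt[!is.na(p) & !p] <- steps[i]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lrsomatic",
    paste0("##FILTER=<ID=", steps, ",Description=\"Failed ", steps,
           " filter\">"),
    "##INFO=<ID=CD,Number=1,Type=Integer,Description=\"Cancer depth\">",
    "##INFO=<ID=CA,Number=1,Type=Integer,Description=\"Cancer alt reads\">",
    "##INFO=<ID=ND,Number=1,Type=Integer,Description=\"Noncancer depth\">",
    "##INFO=<ID=NA,Number=1,Type=Integer,Description=\"Noncancer alt reads\">",
    "##INFO=<ID=VAFC,Number=1,Type=Float,Description=\"Cancer VAF\">",
    "##INFO=<ID=VAFN,Number=1,Type=Float,Description=\"Noncancer VAF\">",
    "##INFO=<ID=MCFC,Number=1,Type=Float,Description=\"Cancer mutated cell fraction\">",
    "##INFO=<ID=MCFN,Number=1,Type=Float,Description=\"Noncancer mutated cell fraction\">",
    "##INFO=<ID=DMCF,Number=1,Type=Float,Description=\"MCFC - MCFN\">",
    "##INFO=<ID=MT,Number=0,Type=Flag,Description=\"Mitochondrial variant\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf(
    "CD=%d;CA=%d;ND=%d;NA=%d;VAFC=%.6g;VAFN=%.6g;MCFC=%.6g;MCFN=%.6g;DMCF=%.6g%s",
    rec$cancer_depth, rec$cancer_alt, rec$noncancer_depth, rec$noncancer_alt,
    rec$vaf_cancer, rec$vaf_noncancer, rec$mcf_cancer, rec$mcf_noncancer,
    rec$delta_mcf, if (mt) ";MT" else "")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  rec$chrom, rec$pos, rec$ref, rec$alt, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_call_vcf
#' @param funnel A funnel data.table from a `call_set`.
#' @export
write_funnel <- function(funnel, path) {
  data.table::fwrite(funnel, path, sep = "\t")
  invisible(path)
}
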