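#' Synthetic dataset configuration
#'
#' Defines the statistical structure of a generated dataset: two cell
#' populations with different library sizes, germline heterozygous
#' sites, cancer-only somatic sites (optionally private to cancer
#' subclones), pure-noise sites under the beta-binomial error model,
#' high-depth mitochondrial variant loci, ambient-RNA
#' cross-contamination, a configurable fraction of mislabelled cells,
#' per-cell fusion detections, empty droplets, and matched scWGS clone
#' counts.  Defaults are desk-scale: 100 cancer + 300 non-cancer cells
#' (roughly the 1:3.6 cancer-to-microenvironment composition of a
#' metastatic tumour biopsy), cancer cells ~4x the library size of
#' non-cancer cells,
#' somatic VAF 0.35 (a typical clonal driver allele fraction under
#' moderate purity/copy state), mitochondrial heteroplasmies at VAF
#' 0.4-0.9 with pseudo-bulk depth far above the 100-read floor, and
#' ambient contamination of 1% of non-cancer reads, which puts
#' non-cancer mitochondrial VAFs at 0.4-0.9% — inside the 0.1-3%
#' window seen in contaminated tumour biopsies.
#'
#' @param n_cancer_cells,n_noncancer_cells Population sizes.
#' @param n_germline_sites,n_somatic_sites,n_noise_sites,n_mt_sites
#'   Site counts per truth class.
#' @param depth_cancer,depth_noncancer Mean per-cell nuclear depth at
#'   a site (negative binomial, dispersion `depth_dispersion`).
#' @param depth_mt_cancer,depth_mt_noncancer Mean per-cell
#'   mitochondrial depth.
#' @param depth_dispersion Negative-binomial size parameter.
#' @param vaf_somatic Allele fraction of somatic sites in carrying
#'   cancer cells.
#' @param vaf_mt_range Range of per-site mitochondrial heteroplasmy in
#'   cancer cells.
#' @param ambient_contamination rho: probability that a non-cancer
#'   cell's read is drawn from the cancer pool (read-level ambient-RNA
#'   mechanism).
#' @param mislabel_fraction Fraction of cancer cells labelled
#'   non-cancer in the input annotation.
#' @param error_params Background sequencing-error [beta_params()];
#'   each (site, cell) draws an error rate from this beta and
#'   distributes error reads uniformly over the three non-reference
#'   bases.
#' @param subclone_fractions Partition of cancer cells into subclones
#'   (must sum to 1).
#' @param subclone_private_sites Number of somatic sites private to
#'   each subclone (same length; remaining somatic sites are clonal).
#' @param n_fusions,fusion_cancer_rate Somatic fusions and their
#'   per-cancer-cell detection rate (non-cancer detections occur at
#'   `ambient_contamination * fusion_cancer_rate`).
#' @param n_artifact_fusions,artifact_fusion_rate Technical-artifact
#'   fusions present at a low rate in both populations.
#' @param n_empty_droplets,droplet_mt_depth,droplet_cancer_fraction
#'   Empty droplets carrying ambient RNA; the fraction of their
#'   mitochondrial reads that is cancer-derived.
#' @param n_aneuploid_cells,n_diploid_cells,scwgs_depth Matched scWGS
#'   clones: cells per pool and mean per-cell depth at a site.
#' @param chrom,min_gap,pos_jitter Nuclear contig name and site
#'   spacing (sites are laid out at least `min_gap` bp apart so that
#'   the close-pair distance filter reflects planted structure, not
#'   layout accidents).
#' @param mt_chrom,mt_length Mitochondrial contig.
#' @param seed Integer seed; the dataset is a deterministic function
#'   of the full configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cancer_cells = 100L, n_noncancer_cells = 300L,
                       n_germline_sites = 20L, n_somatic_sites = 20L,
                       n_noise_sites = 500L, n_mt_sites = 5L,
                       depth_cancer = 8, depth_noncancer = 2,
                       depth_mt_cancer = 500, depth_mt_noncancer = 250,
                       depth_dispersion = 2,
                       vaf_somatic = 0.35, vaf_mt_range = c(0.4, 0.9),
                       ambient_contamination = 0.01,
                       mislabel_fraction = 0.1,
                       error_params = default_beta_params("primary"),
                       subclone_fractions = 1,
                       subclone_private_sites = 0L,
                       n_fusions = 2L, fusion_cancer_rate = 0.3,
                       n_artifact_fusions = 1L,
                       artifact_fusion_rate = 0.02,
                       n_empty_droplets = 50L, droplet_mt_depth = 30,
                       droplet_cancer_fraction = 0.8,
                       n_aneuploid_cells = 20L, n_diploid_cells = 40L,
                       scwgs_depth = 3,
                       chrom = "chr1", min_gap = 12000L,
                       pos_jitter = 8000L,
                       mt_chrom = "chrM", mt_length = 16569L,
                       seed = 7L) {
  cfg <- as.list(environment())
  frac <- c(cfg$ambient_contamination, cfg$mislabel_fraction,
            cfg$fusion_cancer_rate, cfg$artifact_fusion_rate,
            cfg$droplet_cancer_fraction)
  if (any(frac < 0) || any(frac > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(cfg$subclone_fractions) - 1) > 1e-9)
    stop("subclone_fractions must sum to 1")
  if (length(cfg$subclone_private_sites) != length(cfg$subclone_fractions))
    stop("subclone_private_sites must match subclone_fractions in length")
  if (sum(cfg$subclone_private_sites) > cfg$n_somatic_sites)
    stop("more subclone-private sites than somatic sites")
  if (cfg$vaf_somatic < 0 || cfg$vaf_somatic > 1)
    stop("vaf_somatic must lie in [0, 1]")
  cfg$error_params <- as_beta_params(cfg$error_params)
  structure(cfg, class = "sim_config")
}

#' Generate a fully-labelled synthetic dataset
#'
#' Deterministic given the configuration (including its seed):
#' running twice yields identical objects.  Produces a
#' [base_count_table()] (with the mislabelled input annotation and
#' empty-droplet barcodes attached), a per-cell fusion table, matched
#' scWGS clone counts with per-aneuploid-cell alternative counts, a
#' gnomAD-style frequency resource covering the germline sites, and a
#' truth set recording every site class, true cell label and subclone
#' assignment.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `table`, `cell_types` (input labels),
#'   `fusion_calls`, `clone_counts`, `aneuploid_cell_counts`,
#'   `resources`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  a <- cfg$error_params$alpha; b <- cfg$error_params$beta

  ## --- cells -----------------------------------------------------------
  cancer_bc <- sprintf("CELL_C%04d", seq_len(cfg$n_cancer_cells))
  noncancer_bc <- sprintf("CELL_N%04d", seq_len(cfg$n_noncancer_cells))
  n_sub <- length(cfg$subclone_fractions)
  sub_sizes <- diff(round(cumsum(c(0, cfg$subclone_fractions)) *
                            cfg$n_cancer_cells))
  cell_sub <- rep(seq_len(n_sub), sub_sizes)
  n_mis <- round(cfg$mislabel_fraction * cfg$n_cancer_cells)
  mis <- if (n_mis > 0) sample(cancer_bc, n_mis) else character(0)
  cells <- data.table::data.table(
    barcode = c(cancer_bc, noncancer_bc),
    true_label = rep(c("cancer", "noncancer"),
                     c(cfg$n_cancer_cells, cfg$n_noncancer_cells)),
    subclone = c(cell_sub, rep(NA_integer_, cfg$n_noncancer_cells)))
  cells[, mislabeled := barcode %in% mis]
  cells[, input_label := ifelse(mislabeled, "noncancer", true_label)]

  ## --- nuclear sites ---------------------------------------------------
  n_nuc <- cfg$n_germline_sites + cfg$n_somatic_sites + cfg$n_noise_sites
  gaps <- cfg$min_gap + floor(stats::runif(n_nuc, 0, cfg$pos_jitter))
  pos <- cumsum(gaps) + 1000L
  cls <- sample(rep(c("germline", "somatic", "noise"),
                    c(cfg$n_germline_sites, cfg$n_somatic_sites,
                      cfg$n_noise_sites)))
  ref <- sample(bases, n_nuc, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  sites <- data.table::data.table(chrom = cfg$chrom, pos = as.integer(pos),
                                  ref = ref, alt = alt, class = cls,
                                  subclone = NA_integer_)
  som_idx <- which(sites$class == "somatic")
  if (sum(cfg$subclone_private_sites) > 0) {
    priv <- sample(som_idx, sum(cfg$subclone_private_sites))
    sites$subclone[priv] <- rep(seq_len(n_sub), cfg$subclone_private_sites)
  }
  sites[, vaf := ifelse(class == "germline", 0.5,
                        ifelse(class == "somatic", cfg$vaf_somatic, 0))]

  ## --- mitochondrial sites --------------------------------------------
  mt_sites <- if (cfg$n_mt_sites > 0) {
    mpos <- sort(sample(200:(cfg$mt_length - 200L), cfg$n_mt_sites))
    mref <- sample(bases, cfg$n_mt_sites, replace = TRUE)
    malt <- vapply(mref, function(r) sample(setdiff(bases, r), 1L),
                   character(1L))
    data.table::data.table(
      chrom = cfg$mt_chrom, pos = as.integer(mpos), ref = mref, alt = malt,
      class = "mt_somatic", subclone = NA_integer_,
      vaf = stats::runif(cfg$n_mt_sites, cfg$vaf_mt_range[1L],
                         cfg$vaf_mt_range[2L]))
  } else sites[0L]

  ## --- expression counts ----------------------------------------------
  rho <- cfg$ambient_contamination
  gen_counts <- function(site_tab, cell_tab, mu_by_label, droplet = FALSE) {
    ns <- nrow(site_tab); nc <- nrow(cell_tab)
    if (ns == 0L || nc == 0L) return(NULL)
    g <- data.table::CJ(site = seq_len(ns), cell = seq_len(nc))
    st <- site_tab[g$site]; ce <- cell_tab[g$cell]
    mu <- mu_by_label[ce$true_label]
    depth <- stats::rnbinom(nrow(g), mu = mu, size = cfg$depth_dispersion)
    carrier <- if (droplet) rep(TRUE, nrow(g)) else
      ce$true_label == "cancer" &
      (is.na(st$subclone) | st$subclone == ce$subclone)
    # ambient reads are drawn from the whole cancer pool, so a
    # subclone-private allele is diluted by its carrier fraction
    carrier_frac <- ifelse(is.na(st$subclone), 1,
                           cfg$subclone_fractions[st$subclone])
    p_alt <- ifelse(st$class == "germline", 0.5,
                    ifelse(st$vaf > 0 & carrier, st$vaf,
                           ifelse(st$vaf > 0, rho * st$vaf * carrier_frac, 0)))
    if (droplet) p_alt <- ifelse(st$class == "germline", 0.5,
                                 cfg$droplet_cancer_fraction * st$vaf)
    alt_n <- stats::rbinom(nrow(g), depth, p_alt)
    perr <- stats::rbeta(nrow(g), a, b)
    err <- stats::rbinom(nrow(g), depth - alt_n, perr)
    e1 <- stats::rbinom(nrow(g), err, 1 / 3)
    e2 <- stats::rbinom(nrow(g), err - e1, 1 / 2)
    e3 <- err - e1 - e2
    m <- matrix(0L, nrow(g), 4L, dimnames = list(NULL, bases))
    ridx <- match(st$ref, bases)
    rowi <- seq_len(nrow(g))
    m[cbind(rowi, ridx)] <- depth - alt_n - err
    aidx <- match(st$alt, bases)
    m[cbind(rowi, aidx)] <- m[cbind(rowi, aidx)] + alt_n
    # error reads over the three non-reference bases, in base order
    nonref <- t(vapply(ridx, function(i) setdiff(1:4, i), integer(3L)))
    m[cbind(rowi, nonref[, 1L])] <- m[cbind(rowi, nonref[, 1L])] + e1
    m[cbind(rowi, nonref[, 2L])] <- m[cbind(rowi, nonref[, 2L])] + e2
    m[cbind(rowi, nonref[, 3L])] <- m[cbind(rowi, nonref[, 3L])] + e3
    out <- data.table::data.table(
      chrom = st$chrom, pos = st$pos, ref = st$ref,
      barcode = ce$barcode, A = m[, 1L], C = m[, 2L], G = m[, 3L],
      T = m[, 4L], other = 0L)
    out[depth > 0L]
  }

  nuc_counts <- gen_counts(sites, cells,
                           c(cancer = cfg$depth_cancer,
                             noncancer = cfg$depth_noncancer))
  mt_counts <- gen_counts(mt_sites, cells,
                          c(cancer = cfg$depth_mt_cancer,
                            noncancer = cfg$depth_mt_noncancer))
  droplet_bc <- if (cfg$n_empty_droplets > 0)
    sprintf("DROP%04d", seq_len(cfg$n_empty_droplets)) else character(0)
  drop_counts <- if (length(droplet_bc)) {
    dcells <- data.table::data.table(barcode = droplet_bc,
                                     true_label = "droplet",
                                     subclone = NA_integer_)
    gen_counts(mt_sites, dcells, c(droplet = cfg$droplet_mt_depth),
               droplet = TRUE)
  } else NULL

  entries <- data.table::rbindlist(
    Filter(Negate(is.null), list(nuc_counts, mt_counts, drop_counts)))
  input_types <- stats::setNames(cells$input_label, cells$barcode)
  table <- base_count_table(entries, input_types, droplets = droplet_bc)

  ## --- fusions ---------------------------------------------------------
  fus <- list()
  if (cfg$n_fusions > 0) {
    for (i in seq_len(cfg$n_fusions)) {
      nm <- sprintf("FUSA%d--FUSB%d", i, i)
      det_c <- cancer_bc[stats::runif(cfg$n_cancer_cells) <
                           cfg$fusion_cancer_rate]
      det_n <- noncancer_bc[stats::runif(cfg$n_noncancer_cells) <
                              rho * cfg$fusion_cancer_rate]
      fus[[nm]] <- data.table::data.table(fusion_name = nm,
                                          barcode = c(det_c, det_n))
    }
  }
  if (cfg$n_artifact_fusions > 0) {
    for (i in seq_len(cfg$n_artifact_fusions)) {
      nm <- sprintf("ARTA%d--ARTB%d", i, i)
      all_bc <- c(cancer_bc, noncancer_bc)
      det <- all_bc[stats::runif(length(all_bc)) < cfg$artifact_fusion_rate]
      fus[[nm]] <- data.table::data.table(fusion_name = nm, barcode = det)
    }
  }
  fusion_calls <- if (length(fus)) data.table::rbindlist(fus) else
    data.table::data.table(fusion_name = character(), barcode = character())
  fusion_truth <- data.table::data.table(
    fusion_name = names(fus),
    class = rep(c("somatic", "artifact"),
                c(cfg$n_fusions, cfg$n_artifact_fusions))[seq_along(fus)])

  ## --- scWGS clone counts ---------------------------------------------
  all_sites <- data.table::rbindlist(list(sites, mt_sites))
  wgs_cells <- data.table::data.table(
    barcode = c(sprintf("WGS_A%03d", seq_len(cfg$n_aneuploid_cells)),
                sprintf("WGS_D%03d", seq_len(cfg$n_diploid_cells))),
    true_label = rep(c("aneuploid", "diploid"),
                     c(cfg$n_aneuploid_cells, cfg$n_diploid_cells)),
    subclone = NA_integer_)
  # in DNA every somatic site is heterozygous in the aneuploid cells
  wgs_sites <- data.table::copy(all_sites)
  wgs_sites[class %in% c("somatic", "mt_somatic"), vaf := 0.5]
  ns <- nrow(wgs_sites); nc <- nrow(wgs_cells)
  g <- data.table::CJ(site = seq_len(ns), cell = seq_len(nc))
  st <- wgs_sites[g$site]; ce <- wgs_cells[g$cell]
  depth <- stats::rnbinom(nrow(g), mu = cfg$scwgs_depth,
                          size = cfg$depth_dispersion)
  p_alt <- ifelse(st$class == "germline", 0.5,
                  ifelse(st$class %in% c("somatic", "mt_somatic") &
                           ce$true_label == "aneuploid", st$vaf, 0))
  alt_n <- stats::rbinom(nrow(g), depth, p_alt)
  perr <- stats::rbeta(nrow(g), a, b)
  err <- stats::rbinom(nrow(g), depth - alt_n, perr)
  wgs <- data.table::data.table(
    chrom = st$chrom, pos = st$pos, ref = st$ref, alt = st$alt,
    pool = ifelse(ce$true_label == "aneuploid", "aneuploid", "diploid"),
    cell = ce$barcode, depth = depth, alt_reads = alt_n, err = err)
  pools <- wgs[, list(alt_sum = sum(alt_reads), err_sum = sum(err),
                      depth_sum = sum(depth)),
               by = c("chrom", "pos", "ref", "alt", "pool")]
  # error reads reported on the first non-ref, non-alt base
  pm <- matrix(0L, nrow(pools), 4L, dimnames = list(NULL, bases))
  rowi <- seq_len(nrow(pools))
  ridx <- match(pools$ref, bases); aidx <- match(pools$alt, bases)
  pm[cbind(rowi, ridx)] <- pools$depth_sum - pools$alt_sum - pools$err_sum
  pm[cbind(rowi, aidx)] <- pm[cbind(rowi, aidx)] + pools$alt_sum
  eidx <- mapply(function(r, al) setdiff(1:4, c(r, al))[1L], ridx, aidx)
  pm[cbind(rowi, eidx)] <- pm[cbind(rowi, eidx)] + pools$err_sum
  cc <- clone_counts(data.table::data.table(
    chrom = pools$chrom, pos = pools$pos, ref = pools$ref,
    pool = pools$pool, A = pm[, 1L], C = pm[, 2L], G = pm[, 3L],
    T = pm[, 4L], other = 0L))
  aneu_cells <- wgs[pool == "aneuploid" & alt_reads > 0L,
                    c("chrom", "pos", "cell", "alt_reads"), with = FALSE]

  ## --- resources and truth --------------------------------------------
  germ <- sites[class == "germline"]
  gnomad <- if (nrow(germ)) data.table::data.table(
    chrom = germ$chrom, pos = germ$pos, alt = germ$alt,
    af = stats::runif(nrow(germ), 0.05, 0.5)) else NULL
  resources <- annotation_resources(gnomad = gnomad)

  truth <- list(sites = data.table::rbindlist(list(sites, mt_sites)),
                cells = cells, fusions = fusion_truth)
  structure(list(table = table, cell_types = input_types,
                 fusion_calls = fusion_calls, clone_counts = cc,
                 aneuploid_cell_counts = aneu_cells,
                 resources = resources, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_dataset (seed %d): %d cancer + %d noncancer cells ",
    "(%d mislabelled), %d nuclear + %d mt sites, %d fusion rows\n"),
    x$config$seed, x$config$n_cancer_cells, x$config$n_noncancer_cells,
    sum(x$truth$cells$mislabeled), x$config$n_germline_sites +
      x$config$n_somatic_sites + x$config$n_noise_sites,
    x$config$n_mt_sites, nrow(x$fusion_calls)))
  invisible(x)
}

#' Write the truth set as JSON
#' @param truth The `truth` element of a `sim_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Minimal reference consistent with a count table
#'
#' A synthetic reference: each contig is an 'A' run long enough to
#' cover every position in the table, with the table's `ref` bases
#' substituted at their loci (positions whose reference would be 'A'
#' anyway are unaffected).
#'
#' @param table A [base_count_table()].
#' @param pad Extra bases appended past the last locus.
#' @return A named character vector of contig sequences.
#' @export
reference_from_table <- function(table, pad = 10L) {
  dt <- data.table::as.data.table(table)
  loci <- unique(dt[, c("chrom", "pos", "ref"), with = FALSE])
  out <- lapply(split(loci, loci$chrom), function(l) {
    len <- max(l$pos) + pad
    s <- rep("A", len)
    s[l$pos] <- l$ref
    paste(s, collapse = "")
  })
  unlist(out)
}

#' Write a count table as a tagged toy BAM
#'
#' Emits one length-1 read per counted base (base 'N' for `other`),
#' tagged with the cell barcode (`CB`) and a unique UMI (`UB`), at
#' mapping quality 60 and base quality 40, then converts to an
#' indexed, sorted BAM.  Reading the result back with
#' [read_bam_pileup()] (passing the same reference) reproduces the
#' table exactly.
#'
#' @param table A [base_count_table()] (at most `max_reads` reads).
#' @param path Output prefix; `<path>.bam`, `<path>.sam` and
#'   `<path>.fa` are written.
#' @param reference Optional reference (named character /
#'   `DNAStringSet`); built with [reference_from_table()] when absent.
#' @param max_reads Safety cap on the number of reads.
#' @return list with `bam`, `sam`, `fasta` paths and the `reference`
#'   used, invisibly.
#' @export
write_toy_bam <- function(table, path, reference = NULL,
                          max_reads = 100000L) {
  dt <- data.table::as.data.table(table)
  total <- sum(dt$A + dt$C + dt$G + dt$T + dt$other)
  if (total > max_reads)
    stop("table holds ", total, " reads; toy BAM export caps at ", max_reads)
  if (is.null(reference)) reference <- reference_from_table(table)
  if (inherits(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  if (nrow(dt)) {
    mx <- dt[, list(m = max(pos)), by = "chrom"]
    short <- mx$m > nchar(reference[mx$chrom])
    if (any(is.na(nchar(reference[mx$chrom]))) || any(short))
      stop("reference shorter than the maximum table position")
  }
  recs <- list()
  for (base in c("A", "C", "G", "T", "other")) {
    n <- dt[[base]]
    if (!sum(n)) next
    idx <- rep(seq_len(nrow(dt)), n)
    recs[[base]] <- data.table::data.table(
      chrom = dt$chrom[idx], pos = dt$pos[idx], barcode = dt$barcode[idx],
      base = if (base == "other") "N" else base)
  }
  reads <- if (length(recs)) data.table::rbindlist(recs) else
    data.table::data.table(chrom = character(), pos = integer(),
                           barcode = character(), base = character())
  sam_path <- paste0(path, ".sam")
  fa_path <- paste0(path, ".fa")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   nchar(reference)))
  body <- if (nrow(reads)) sprintf(
    "r%06d\t0\t%s\t%d\t60\t1M\t*\t0\t0\t%s\tI\tCB:Z:%s\tUB:Z:u%06d",
    seq_len(nrow(reads)), reads$chrom, reads$pos, reads$base,
    reads$barcode, seq_len(nrow(reads))) else character(0)
  writeLines(c(hdr, body), sam_path)
  writeLines(paste0(">", names(reference), "\n", reference), fa_path)
  bam <- Rsamtools::asBam(sam_path, destination = path, overwrite = TRUE,
                          indexDestination = TRUE)
  invisible(list(bam = bam, sam = sam_path, fasta = fa_path,
                 reference = reference))
}
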