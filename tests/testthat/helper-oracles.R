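# Independent oracles and small fixture builders shared across tests.

# Beta-binomial tail probabilities for k = 0..n via a multiplicative
# pmf recurrence -- an arithmetic route independent of the log-gamma
# implementation under test.
oracle_bb_tails <- function(n, a, b) {
  pmf <- numeric(n + 1L)
  pmf[1L] <- if (n == 0L) 1 else prod((b + 0:(n - 1L)) / (a + b + 0:(n - 1L)))
  if (n > 0L) {
    for (j in 0:(n - 1L)) {
      pmf[j + 2L] <- pmf[j + 1L] * (n - j) / (j + 1L) * (a + j) / (b + n - j - 1L)
    }
  }
  rev(cumsum(rev(pmf)))  # tails[k+1] = P(X >= k)
}

oracle_bb_tail <- function(k, n, a, b) oracle_bb_tails(n, a, b)[k + 1L]

# O(n^2) brute-force close-pair removal (both members of a pair at
# distance <= min_distance on the same chromosome are dropped)
oracle_distance_keep <- function(chrom, pos, min_distance = 10000L) {
  n <- length(pos)
  keep <- rep(TRUE, n)
  if (n < 2L) return(keep)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= min_distance) {
        keep[i] <- FALSE; keep[j] <- FALSE
      }
    }
  }
  keep
}

# one variant record per row, defaulting to values that pass every
# per-record nuclear filter; tests flip one aspect at a time
make_records <- function(n = 1L, chrom = "chr1",
                         pos = seq(100000L, by = 50000L, length.out = n),
                         ref = "A", alt = "G",
                         cancer_alt = 20L, cancer_depth = 40L,
                         cancer_nonref = cancer_alt,
                         noncancer_alt = 0L, noncancer_depth = 40L,
                         n_cancer_cells_alt3 = 5L,
                         mcf_cancer = 0.8, mcf_noncancer = 0.05) {
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    cancer_alt = as.integer(cancer_alt),
    cancer_depth = as.integer(cancer_depth),
    cancer_nonref = as.integer(cancer_nonref),
    noncancer_depth = as.integer(noncancer_depth),
    noncancer_alt = as.integer(noncancer_alt),
    vaf_cancer = cancer_alt / pmax(cancer_depth, 1L),
    vaf_noncancer = noncancer_alt / pmax(noncancer_depth, 1L),
    n_cancer_cells_alt3 = as.integer(n_cancer_cells_alt3),
    mcf_cancer = mcf_cancer, mcf_noncancer = mcf_noncancer,
    delta_mcf = mcf_cancer - mcf_noncancer)
}

# a small random count table over a handful of loci and cells
random_count_table <- function(seed, n_loci = 8L, n_cells = 5L,
                               chroms = c("chr1", "chr2")) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  loci <- data.table::data.table(
    chrom = sample(chroms, n_loci, replace = TRUE),
    pos = sample(1000:5000, n_loci),
    ref = sample(bases, n_loci, replace = TRUE))
  loci <- unique(loci, by = c("chrom", "pos"))
  cells <- sprintf("BC%02d", seq_len(n_cells))
  g <- data.table::CJ(i = seq_len(nrow(loci)), cell = seq_len(n_cells))
  cnt <- matrix(rpois(nrow(g) * 5L, 2), ncol = 5L)
  dt <- data.table::data.table(
    chrom = loci$chrom[g$i], pos = loci$pos[g$i], ref = loci$ref[g$i],
    barcode = cells[g$cell], A = cnt[, 1L], C = cnt[, 2L], G = cnt[, 3L],
    T = cnt[, 4L], other = cnt[, 5L])
  dt <- dt[(A + C + G + T + other) > 0L]
  ct <- stats::setNames(rep(c("cancer", "noncancer"), length.out = n_cells),
                        cells)
  base_count_table(dt, ct)
}

sorted_counts <- function(tab) {
  # rebuild column by column so that table-level attributes (min_mq,
  # skip logs) do not leak into the comparison
  dt <- data.table::data.table(
    chrom = tab$chrom, pos = tab$pos, ref = tab$ref, barcode = tab$barcode,
    A = tab$A, C = tab$C, G = tab$G, T = tab$T, other = tab$other)
  data.table::setkeyv(dt, c("chrom", "pos", "barcode"))
  dt[]
}

# default-scale simulated dataset, cached per seed within a test run
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 7L, ...) {
  key <- paste0("s", seed, "_", paste(deparse(substitute(list(...))),
                                      collapse = ""))
  if (is.null(sim_cache[[key]]))
    sim_cache[[key]] <- simulate_dataset(sim_config(seed = seed, ...))
  sim_cache[[key]]
}

quiet_pipeline <- function(...) suppressWarnings(run_pipeline(...))
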