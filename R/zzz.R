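#' @import data.table
#' @importFrom stats setNames rnbinom rbinom rbeta runif optim
#' @importFrom utils head modifyList
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "A", "C", "G", "T", "other", "alt", "alt_reads",
  "barcode", "cancer_alt", "cancer_depth", "cancer_nonref", "chrom",
  "class", "delta_mcf", "depth", "depth_sum", "fusion_name", "genotype",
  "label", "mcf", "mcf_cancer", "mcf_noncancer", "n", "n_cancer",
  "n_cancer_cells_alt3", "n_cells_covered", "n_covered", "n_mutated",
  "n_noncancer", "no_coverage", "noncancer_alt", "noncancer_depth",
  "pass_distance", "pool", "pos", "ref", "ref_reads", "somatic", "subclone",
  "vaf", "vaf_cancer", "vaf_noncancer", "variant", "mislabeled",
  "input_label", "true_label", "cell", "w", "err"))
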