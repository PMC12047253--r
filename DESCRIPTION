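Package: lrsomatic
Title: Somatic Variant Selection from Long-Read Single-Cell RNA-Seq
    Without a Matched Normal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: De novo selection of somatic single-nucleotide variants
    (nuclear and mitochondrial) and gene fusions from barcoded long-read
    single-cell RNA-seq of tumour biopsies, using non-cancer cells from
    the same biopsy as a pseudo-normal instead of a matched normal
    sample.  Background sequencing error is modelled with a beta-binomial
    distribution fitted at homozygous-reference sites; candidate loci are
    screened through an ordered battery of coverage, noise, artifact and
    germline filters with a full per-filter ledger.  Before definitive
    calling, marker-gene cell-type labels are corrected by reannotating
    each cell from its mutational profile over high-confidence cancer
    variants, which rescues somatic variants otherwise discarded as
    germline when cancer cells are mislabelled.  Mitochondrial variants
    are called under contamination-robust rules that tolerate ambient
    cancer RNA in the tumour microenvironment.  Includes single-cell
    genotyping, export of a cell-by-variant matrix for clonal
    reconstruction, validation against single-cell whole-genome
    sequencing clone counts, and a fully-labelled synthetic data
    generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Rsamtools,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    withr
Config/testthat/edition: 3
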