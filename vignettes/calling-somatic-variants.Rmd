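---
title: "Calling somatic variants in long-read scRNA-seq without a matched normal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic variants in long-read scRNA-seq without a matched normal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrsomatic)
```

## The problem

Tumour biopsies profiled with droplet-based long-read single-cell
RNA-seq contain both cancer cells and microenvironment ("non-cancer")
cells. Because matched normal tissue is rarely available, the
non-cancer cells of the same biopsy serve as a pseudo-normal:
a variant present in cancer cells but absent from non-cancer cells is
somatic, one present in both is germline. This logic fails in two
characteristic ways that this package is built around:

1. **Cell-type misannotation.** Labels derived from marker-gene
   expression are imperfect. Every cancer cell mislabelled as
   non-cancer leaks cancer alleles into the pseudo-normal, and true
   somatic variants are then discarded as germline. The package
   therefore *reannotates* cell types from mutational profiles before
   definitive calling.
2. **Ambient RNA.** RNA released by dead or dying cancer cells is
   co-encapsulated with non-cancer cells. The effect is strongest for
   mitochondrial RNA, where non-cancer cells routinely show the cancer
   allele at low fraction (of the order of 0.1–3% per cell).
   Mitochondrial variants therefore run a dedicated, contamination-
   robust filter battery instead of the nuclear germline test.

## The error model

All statistical decisions reduce to one test. Non-reference read
counts at error-only sites are modelled as binomial with a
site-specific error rate $P$ that itself follows a Beta distribution:

$$ k \mid n, P \sim \mathrm{Binomial}(n, P), \qquad
   P \sim \mathrm{Beta}(\alpha, \beta), $$

so that marginally $k \sim \mathrm{BetaBinomial}(n, \alpha, \beta)$.
An observed count is "significantly above background" when the
one-sided tail $P(X \ge k)$ falls strictly below the test's level.
The tail is computed by summing the exact probability mass function on
the log-gamma scale, accumulating whichever side of the distribution
is smaller for accuracy; `bb_tail(0, n)` is exactly 1 and the tail is
non-increasing in $k$.

Two parameter sets are maintained, mirroring the convention of
pseudo-bulk error models for this data type: a *primary* set
($\alpha = 0.21$, $\beta = 104.95$; mean error rate $2\times10^{-3}$)
used for the noise, germline, panel-of-normals, genotyping and scWGS
tests, and an *other-allele* set ($\alpha = 0.25$, $\beta = 162.04$)
used only for the residual non-reference alleles at a candidate locus.
These are shipped defaults appropriate for PacBio-grade long reads;
`fit_background()` refits them from homozygous-reference sites by
maximum likelihood with a method-of-moments start. The defining
criteria for fitting sites (pseudo-bulk VAF below 0.05, depth at least
10, subsampled to at most 500,000 sites under a fixed seed) are a
declared choice of this package: no published convention fixes them.

## The two-pass workflow

`run_pipeline()` orchestrates two passes.

**Pass 1 — high-confidence cancer variants and reannotation.**
Candidates are detected from the cancer pseudo-bulk (at least one
alternative read and five reads of coverage; the most frequent
non-reference base is the alternative allele, ties resolved in base
order A < C < G < T). A stringent pre-filter keeps *high-confidence
cancer variants* (HCCVs): pseudo-bulk depth of at least 20 in both
populations, a clean other-allele test, no homopolymer/editing/
panel/population-frequency evidence, non-cancer VAF below 0.2, and
$\Delta\mathrm{MCF} > 0.4$, where the mutated cell fraction (MCF) is
the fraction of mutated cells among cells with at least one read at
the position and $\Delta\mathrm{MCF} =
\mathrm{MCF}_{cancer} - \mathrm{MCF}_{noncancer}$. Tolerating a
non-zero non-cancer VAF is deliberate: it is exactly what mislabelled
cancer cells produce. Each cell is then genotyped over the HCCVs;
cells covering fewer than 3 are set aside (`"filtered"`, excluded from
both pseudo-bulks downstream), and cells with at least 25% of covered
HCCVs mutated become cancer.

Two open points in this chain were resolved as follows. The HCCV
written description enumerates the retention rule ambiguously; we keep
a variant iff VAF~noncancer~ < 0.2 **and** ΔMCF > 0.4, since HCCVs
must be cancer-enriched by construction. Mitochondrial HCCVs run the
same chain minus the close-pair rule, with only the long-read panel of
normals applied (a short-read panel does not represent long-read
mitochondrial artifacts); the RNA-editing filter is retained. The
per-cell "mutated" tally reuses the single-cell genotyping rules
described below.

**Pass 2 — definitive calling.** Candidates are re-detected from the
reannotated pseudo-bulks and pass an ordered battery of ten filters:
coverage (≥ 5 reads in both pseudo-bulks), cell-level support (≥ 3
alternative reads in ≥ 2 cancer cells), the noise test in cancer
(level 0.001), the other-allele test (0.05), homopolymer proximity,
RNA-editing sites, short-/long-read panels of normals, the germline
test in non-cancer cells (level 0.05 — deliberately *looser as a
p-value cutoff and therefore stricter as a germline filter* than the
0.001 a pure noise test would use), population frequency (≥ 1%
fails), and finally the close-pair rule: any two surviving loci within
10,000 bp on one chromosome are *both* removed, since such pairs are
enriched for alignment artifacts and allele-specific expression.
Filters 1–9 are per-record and commute; the ledger order is fixed for
reporting only, and the funnel satisfies
$\mathrm{pass}_i = \mathrm{pass}_{i-1} - \mathrm{fail}_i$ at every
step. Candidates on mitochondrial contigs (`chrM`/`MT`/`chrMT`,
configurable) are routed to the mitochondrial battery: coverage ≥ 100
in both pseudo-bulks, population frequency, ΔMCF ≥ 0.35, cancer VAF
≥ 0.1. Candidate detection itself is counted as the battery's
implicit first step. Fusions, consumed as an external per-cell
detection table, are somatic when present in more than 5% of cancer
cells and fewer than 1% of non-cancer cells — the tolerance again
reflects ambient reads.

All significance thresholds are strict (`p < level`; a p-value exactly
at the level does not reject) and all count/fraction thresholds are
inclusive where phrased "at least". Every number above is a field of
`calling_thresholds()`.

## Genotyping and the cell–variant matrix

A cell is mutated at a nuclear SNV when the tail test on its
alternative versus reference reads is significant at 0.01, missing
when it has neither. At a mitochondrial SNV the rule is a hard
per-cell VAF threshold (> 0.3, strict), because the error-model test
would call contaminated non-cancer cells mutated at mitochondrial
depths. `build_matrix()` assembles the variants-by-cells genotype
matrix for clonal reconstruction (1 = mutated, 0 = wildtype, 3 =
missing): SNV/mtSNV rows need non-missing entries in at least five
cells, fusion rows detections in at least three, and cells with fewer
than three non-missing entries are dropped; rows and columns are
re-checked to a fixed point (the written procedure states one order
only — rows, then cells — and the fixed-point pass makes the result
order-insensitive). mtSNV rows use the SNV row rule since they are
SNVs; this is configurable. Clustering itself (e.g. Bayesian
non-parametric clustering) is out of scope; the matrix TSV is its
input format.

## scWGS validation

Given pooled aneuploid (cancer) and diploid (non-cancer) scWGS clone
counts, `classify_support()` labels each called locus somatic
(significant in the aneuploid pool only, level 0.01), germline
(significant in the diploid pool), uncalled, or ineligible — a locus
is eligible when it has at least one mutated read *or* at least 17
reads of coverage, implemented exactly as stated despite the
asymmetry. `call_scwgs_denovo()` builds an independent truth set with
its own printed thresholds (aneuploid $p < 0.001$ and diploid
$p > 0.05$, five reads in both scRNA pseudo-bulks and both pools, and
— when per-cell counts are available — three mutated reads in two
aneuploid cells; with pooled-only input that sub-filter is skipped
with a message). The two operations keep their different levels
deliberately. `performance()` reports precision, sensitivity and F1;
with no calls, precision is undefined and reported as 0 with a flag.

## The synthetic data generator

`simulate_dataset()` is a first-class module, not a fixture: it
generates the statistical structure every upstream module assumes,
with a truth set. Its defaults define the study conditions used
throughout the test suite, chosen once as follows:

* **Populations**: 100 cancer + 300 non-cancer cells — a typical
  biopsy composition at desk scale — with per-cell, per-site nuclear
  depths drawn from a negative binomial (means 8 and 2, dispersion 2),
  reflecting the roughly 3.6-fold library-size advantage of cancer
  cells in the data type this emulates. Any over-dispersed count law
  would do; both means and the dispersion are configuration keys.
* **Sites**: 20 germline heterozygous (allele fraction 0.5 in all
  cells, entered into the generated population-frequency resource), 20
  somatic (VAF 0.35 in carrying cancer cells — a clonal driver-like
  allele fraction under moderate purity), 500 error-only sites, and 5
  mitochondrial variants with heteroplasmy drawn from U(0.4, 0.9) at
  mitochondrial depths (means 500/250 per cell), comfortably above the
  100-read pseudo-bulk floor. Sites are laid out at least 12 kb apart
  so the close-pair filter reflects planted structure rather than
  layout accidents.
* **Errors**: every (site, cell) draws an error rate from the shipped
  Beta(0.21, 104.95) and distributes error reads uniformly over the
  three non-reference bases.
* **Contamination**: each non-cancer read is cancer-derived with
  probability $\rho$ (read-level ambient-RNA mechanism; for
  subclone-private alleles the ambient pool is diluted by the carrier
  fraction). The default $\rho = 0.01$ puts non-cancer mitochondrial
  VAFs at 0.4–0.9%, inside the 0.1–3% window reported for
  contaminated biopsies; nuclear ambient levels in practice are lower
  than mitochondrial ones, so a single read-level $\rho$ at the low
  end of that window is the realistic compromise. A design-time power
  analysis of the germline tail test fixed this choice: at
  $\rho = 0.01$ and VAF 0.35 the expected contaminated non-cancer
  allele fraction (~0.004) leaves the germline test far from its 0.05
  level, while by $\rho \approx 0.03$ mitochondrial-depth profiles are
  reliably rejected — the dichotomy the dedicated mitochondrial path
  exists to fix, and a property the test suite asserts.
* **Mislabelling**: 10% of cancer cells carry a non-cancer input
  label (their reads, and hence mutational profiles, are unchanged).
* **Fusions**: two somatic fusions detected in 30% of cancer cells
  (ambient rate $\rho \times 30\%$ in non-cancer cells) plus one
  artifact fusion at 2% everywhere.
* **Matched scWGS**: 20 aneuploid and 40 diploid cells at mean
  per-cell depth 3; somatic sites are heterozygous (VAF 0.5) in
  aneuploid DNA; per-aneuploid-cell alternative counts are emitted for
  the de novo truth-set sub-filter.
* **Empty droplets**: 50 droplets whose mitochondrial reads are 80%
  cancer-derived, for the ambient-RNA diagnostics.

Everything is a deterministic function of the configuration,
including its seed. What the generator does *not* emulate — and what
green tests therefore do not demonstrate about real data — includes:
per-cell library-size factors (depths are i.i.d. across cells), UMI
duplication structure, intron/exon coverage geometry and intrapriming,
strand effects, position-dependent error profiles, homopolymer and
editing artifacts (those filters are exercised with crafted fixtures
instead), copy-number alterations, and doublets.

The suite runs the generator at this default scale (about 220,000
site-by-cell draws per dataset), which keeps a full two-pass pipeline
run to a few seconds; the whole-package checks use single-seed runs
for the headline call-quality properties and 3–5 seeds for the
stochastic ordering properties.

## Numerical and degenerate-input choices

* Tail sums accumulate the smaller side of the pmf; `bb_tail(0, n)`
  returns 1 exactly.
* The ML fit collapses duplicate (k, n) pairs, optimizes
  log-parameters by Nelder–Mead from a method-of-moments start, and
  falls back to the shipped defaults (with a warning) when all
  non-reference counts are zero; fewer than 1,000 usable sites is an
  error that names the alternative.
* The other-allele test with zero residual depth passes vacuously.
* The homopolymer rule — grammatically ambiguous in prose
  descriptions of this filter family — is implemented as: a tract is
  a run of ≥ 4 identical reference bases; a variant fails when inside
  the tract or within 4 bp of either end. Both numbers are
  configuration keys. Tract intervals are stored 1-based, half-open;
  all locus coordinates are 1-based and closed, matching VCF.
* Multi-allelic candidates collapse to the most frequent alternative
  allele (ties in base order); every downstream statistic is
  biallelic.
* The close-pair filter removes both members of a pair, is symmetric
  and order-independent, and is applied to step-1–9 survivors only.
* An empty candidate set yields an empty call set with an all-zero
  funnel; an empty cell group yields an empty pseudo-bulk with a
  warning; unknown fusion barcodes are dropped with a warning.
* Insertions and deletions are never counted as alternative alleles;
  secondary, supplementary, duplicate and unmapped alignments are
  skipped at pileup, as are reads without a barcode tag (tallied in a
  skip log). Cell barcodes are read from `CB` with `XC` fallback,
  UMIs from `UB`/`XM`; both are configurable. The pileup base-quality
  floor defaults to Q20 — the read-quality regime this workflow
  expects — and the mapping-quality floor to 60, the maximum the
  intended long-read aligner emits.

## Known limitations

The caller is biallelic and SNV-only (no indels, no phasing, no
functional annotation). The recommended operating scale — two billion
mapped bases per cell type, five reads per locus per cell type — is
enforced as a warning, not an error, and desk-scale synthetic runs
operate far below it. The pileup reader is written for the toy BAM
scale used in testing and validation; for production-size BAMs,
pre-computed per-cell count tables are the intended input. Thresholds
were tuned for high-quality (≥ Q20) long reads; lower-quality
chemistries need the documented threshold overrides.
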