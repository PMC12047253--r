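# lrsomatic

De novo somatic variant selection from barcoded long-read single-cell
RNA-seq of tumour biopsies — **without a matched normal sample**.
Non-cancer cells captured in the same biopsy serve as a pseudo-normal;
the package is built around the two failure modes of that idea:
cell-type misannotation (which turns true somatic variants into
false-negative "germline" calls) and ambient cancer RNA (which
contaminates non-cancer cells, most severely on the mitochondrial
genome). It is aimed at computational biologists analysing
tumour/microenvironment scRNA-seq who want somatic SNVs, mitochondrial
SNVs and fusions from the same cells, plus a cell-by-variant genotype
matrix ready for clonal reconstruction.

## The model in brief

Non-reference read counts at error-only sites follow a beta-binomial:
`k | n, P ~ Binomial(n, P)` with `P ~ Beta(α, β)`, fitted at
homozygous-reference sites (shipped long-read defaults
`α = 0.21, β = 104.95`, plus an other-allele set `0.25 / 162.04`).
Every decision is a one-sided tail test `P(X ≥ k)` at a strict level.
Candidate loci from the cancer pseudo-bulk pass an ordered battery of
ten filters (coverage, per-cell support, noise, other-allele noise,
homopolymers, RNA-editing sites, panels of normals, the germline test
in non-cancer cells, population frequency ≥ 1%, and a 10 kb
close-pair rule). Before definitive calling, cell types are
*reannotated*: high-confidence cancer variants (HCCVs) are selected
with stringent coverage/enrichment rules — notably non-cancer VAF
< 0.2 and ΔMCF > 0.4, where the mutated cell fraction MCF counts
mutated cells among covered cells and ΔMCF = MCF_cancer −
MCF_noncancer — and any cell with ≥ 25% of its covered HCCVs mutated
becomes cancer. Mitochondrial SNVs run a dedicated
contamination-robust battery (depth ≥ 100 in both pseudo-bulks,
population frequency, ΔMCF ≥ 0.35, cancer VAF ≥ 0.1) because the
nuclear germline filter rejects exactly the loci that ambient mtRNA
contaminates. Details, defaults and design decisions are in the
vignette `vignettes/calling-somatic-variants.Rmd`.

## Worked example

The package ships a first-class synthetic data generator whose
defaults emulate a desk-scale tumour biopsy (100 cancer + 300
non-cancer cells, 10% of cancer cells mislabelled, ambient
contamination, mitochondrial heteroplasmies, fusions, matched scWGS
clone counts, and a truth set):

```r
library(lrsomatic)

sim <- simulate_dataset(sim_config(seed = 7))
sim
#> sim_dataset (seed 7): 100 cancer + 300 noncancer cells (10 mislabelled),
#>   540 nuclear + 5 mt sites, 73 fusion rows

res <- run_pipeline(sim$table, sim$cell_types, sim$resources,
                    sim$fusion_calls)
res
#> pipeline_result
#>   reannotation: 400 cells -> 100 cancer / 300 noncancer / 0 filtered
#>   somatic SNVs: 20 of 437 candidates
#>   somatic mtSNVs: 5 of 5 candidates
#>   somatic fusions: 2
#>   cell-variant matrix: 27 x 400
```

All 10 mislabelled cells are relabelled cancer, the 20 planted somatic
SNVs and 5 mitochondrial variants are recovered, and no planted
germline site survives:

```r
str(evaluate_calls(res, sim$truth))
#> $ snv              : tp 20, fp 0, fn 0, precision 1, sensitivity 1, f1 1
#> $ n_germline_called: int 0
#> $ mt_sensitivity   : num 1
```

The per-step funnel shows where candidates die — here the 397 loci
without multi-cell alternative support (mostly error-only sites) and
the 20 planted germline sites at the germline step:

```r
res$snv$funnel
#>             step  n_in n_pass n_fail
#>  1:     coverage   437    437      0
#>  2:  alt_support   437     40    397
#>  3: noise_cancer    40     40      0
#>  ...
#>  8:     germline    40     20     20
#>  9:       gnomad    20     20      0
#> 10:     distance    20     20      0
```

`run_pipeline(..., out_dir = "out/")` additionally writes VCFs, the
funnel, the reannotation table, selected fusions, the cell-variant
matrix (1 = mutated, 0 = wildtype, 3 = missing) and, when scWGS clone
counts are supplied, support labels and benchmark metrics. A thin
command-line front end is installed under `exec/`:

```sh
lrsomatic simulate --out sim/ --seed 7
lrsomatic run --counts sim/counts.tsv --cell-types sim/cell_types.tsv \
              --droplets sim/droplets.txt --fusions sim/fusions.tsv \
              --gnomad sim/gnomad.tsv --scwgs sim/scwgs_clones.tsv --out out/
```

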