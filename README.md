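# barcodegap

Quantifies how well DNA barcode loci discriminate species in a densely
sampled clade — the situation where barcoding is hardest and where
genus-wide surveys tend to overstate its power. Given per-locus multiple
sequence alignments and a sample metadata table (species, clade path,
region, representative flag), the package evaluates each locus and locus
combination globally, within named subclades, and within geographic
regions, using two complementary measures:

* **Character view** — accessions are collapsed into unique haplotypes
  (zero-mismatch connected components, with gaps treated either as missing
  data or as a fifth character state) and the **maximum identification
  rate** is `100 · n_unique / n_species`, the ceiling on discrimination
  when a single substitution counts.
* **Distance view** — pairwise **Kimura 2-parameter** distances with
  pairwise deletion,
  `d = −½ · ln[(1 − 2P − Q)·√(1 − 2Q)]`
  (P, Q the transition and transversion proportions), are split into
  intraspecific and interspecific sets (one representative accession per
  species for the latter), summarised, compared against the 1% and 2%
  thresholds, and tested for a **barcoding gap** — whether the smallest
  interspecific distance exceeds the largest intraspecific one.

A synthetic-data generator (ultrametric nested-clade Yule trees, exact
K80 site evolution with locus-specific rates, uneven accession sampling,
indel runs, terminal missing data) provides calibrated inputs so the whole
pipeline is testable offline; see the methods vignette
(`vignettes/barcode-evaluation.Rmd`) for the models, defaults and their
rationale.

## Worked example

```r
library(barcodegap)

sim <- simulate_barcode_data(simulation_config(seed = 1))  # 112 species, 6 loci
bundle <- run_evaluate(
  sim$aset,
  combinations = list("rbcL", c("rbcL", "matK"), c("rbcL", "matK", "nrITS")),
  subsets = list(list(clade = "CladeB")))
bundle
#> evaluation_bundle: 6 report rows
#>   rbcL                         [global]          species 112  maxID  28.57%  inter mean 0.0058
#>   rbcL                         [clade:CladeB]    species  28  maxID  28.57%  inter mean 0.0026
#>   rbcL+matK                    [global]          species 112  maxID  63.39%  inter mean 0.0077
#>   rbcL+matK                    [clade:CladeB]    species  28  maxID  64.29%  inter mean 0.0040
#>   rbcL+matK+nrITS              [global]          species 112  maxID  91.96%  inter mean 0.0229
#>   rbcL+matK+nrITS              [clade:CladeB]    species  28  maxID 100.00%  inter mean 0.0117

bundle$reports[[2]]
#> discrimination_report: rbcL [clade:CladeB]
#>   species 28 | 491 sites | 9 variable | unique 8 (8 as 5th state) | max ID 28.57%
#>   inter: mean 0.0026 (SD 0.0027), max 0.0144 | >1%: 2.12% | >2%: 0.00%
#>   intra: mean 0.0005 (SD 0.0008), max 0.0044 over 15 species / 64 accessions
#>   barcoding gap: no (margin -0.0044)
```

Reading the rows: the slow core-barcode component rbcL resolves under a
third of the species even before distances are considered; concatenating
matK roughly doubles the ceiling; adding the fast nuclear spacer nrITS
takes it above 90%. Restricting to a 28-species subclade cuts mean
interspecific divergence roughly in half (0.0077 → 0.0040 for the
two-locus barcode), the close-relative effect the stratified evaluation
exists to measure. The report for one cell shows the full row: variable
sites, haplotype counts under both gap conventions, distance summaries,
threshold percentages, and the (absent) barcoding gap.

`run_evaluate(..., out = "dir")` additionally writes `report.tsv` in the
standard table layout (`Gene Region`, `Species`, `Aligned Length`,
`Variable characters`, `Unique sequences`, `% Max ID rate`, `Max`,
`Mean (SD)`, `> 1%`, `> 2%`), per-dataset intra/inter histogram TSVs, and
a `run.log` of skipped strata and undefined-distance exclusions. Real data
enter through `read_fasta_alignment()` + `read_metadata()` +
`alignment_set()`, or a directory via `read_input_bundle()`; a thin
command-line wrapper lives at `inst/scripts/barcode_eval.R`.

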