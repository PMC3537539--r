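# barcodegap

Distance-based assessment of species limits from aligned DNA barcodes
(the ~658 bp COI fragment), for taxonomists and biodiversity researchers
building reference libraries: does each morphospecies own an exclusive,
well-supported barcode cluster, which divergence threshold best
discriminates species, and which taxa show anomalous divergences that
warrant morphological reassessment?

## What it computes

* **Quality control** — sequenced length ≥ 600 bp, missing nucleotides
  < 1%, stop-codon check under the invertebrate mitochondrial code.
* **Distances** — Kimura 2-parameter
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` (and p-distances) with
  *pairwise deletion* of gaps/missing data; saturated pairs are reported
  undefined, never clamped.
* **Barcode-gap summaries** — per species: maximum/mean intraspecific
  distance, haplotype count, nearest-neighbour (NN) minimum
  interspecific distance; flags `OVERLAP` (max intra ≥ min inter),
  `HIGH_INTRA` (> 2%), `LOW_INTER` (< 2%); gap histograms in 0.25% bins.
* **Clustering** — deterministic neighbour-joining tree, per-species
  monophyly on unrooted bipartitions, column-bootstrap support.
* **Thresholds** — single-linkage clustering swept over 0.1–3.0%
  (0.1% steps), counting erroneously lumped and split species, the
  optimal identification threshold, and the best species-richness
  threshold.
* **Reassessment** — replayable RENAME/SPLIT/LUMP/EXCLUDE change sets
  with audited application and pre/post comparison tables; assignment of
  `UNKNOWN` specimens by nearest neighbour plus cluster exclusivity.
* **Auxiliary inference** — one-tailed locality permutation test on
  maximum intraspecific distances; OLS regression of max intra on
  sample size.
* **Synthetic data** — a seeded generator of COI-like alignments with
  known species structure and planted anomalies (misidentifications,
  cryptic splits, shared haplotypes), so the whole pipeline is testable
  without downloads.

## Worked example

```r
library(barcodegap)

sim <- simulate_barcodes(sim_params(n_species = 12, seed = 7))
fit <- barcode_gap(sim$alignment, sim$specimens, bootstrap = 100, seed = 7)
summary(fit)
#> Barcode-gap species-limits analysis (K2P distances)
#>   81 specimens retained (0 removed by QC), 12 species
#>   optimal threshold 0.5% (success 83.3%); richness threshold 0.5%
#>   12/12 species monophyletic on the NJ tree
#>   max intraspecific: range 0.15-0.92% (mean of maxima 0.49%), 10 species with n >= 2
#>   nearest-neighbour interspecific: range 0.46-7.41% (mean 3.43%)
#>   flagged taxa: Species_005, Species_012
#>   bootstrap: 10/12 species with support >= 95% (B = 100)
```

All twelve species are monophyletic, but the closest pair
(`Species_005` / `Species_012`, NN distance 0.46%) sits below the 2%
cutoff and is flagged `LOW_INTER` for review; a 0.5% single-linkage
threshold classifies 83.3% of species perfectly (the flagged pair lumps
below it, and species with intraspecific variation above it split).
Per-species detail lives in `fit$summaries`:

```r
head(fit$summaries[, c("species", "n_specimens", "max_intra", "min_inter", "nn_species")])
#>       species n_specimens max_intra min_inter  nn_species
#> 1 Species_001           9 0.6104580 2.4743806 Species_011
#> 2 Species_002           4 0.6104580 7.3893278 Species_003
#> 3 Species_003           1        NA 5.2239187 Species_010
#> ...
```

`plot(fit)` draws the gap histogram and the lump/split/success curves;
`run_pipeline()` executes the same workflow over a FASTA + specimen TSV
and writes every table, the Newick tree, and a config echo into an
output directory.  A thin command-line dispatcher with `simulate`,
`qc`, `dist`, `summarize`, `tree`, `sweep`, `reassess`, `stats` and
`run` subcommands ships in `inst/cli/barcodegap.R`.

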