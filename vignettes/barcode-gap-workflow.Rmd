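---
title: "Species limits from DNA barcodes: the barcodegap workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species limits from DNA barcodes: the barcodegap workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

DNA barcoding identifies specimens by comparing a standard mitochondrial
fragment (the ~658 bp 5' region of COI) against a reference library of
determined individuals.  Whether that works for a given group hinges on
the *barcode gap*: intraspecific divergences must sit below the distance
separating each species from its nearest relative.  In well-populated
surveys of closely related species the two distributions typically
overlap, so practitioners combine three complementary criteria:

1. **Cluster monophyly with bootstrap support** — do all conspecifics
   form an exclusive cluster on a neighbour-joining (NJ) tree, and how
   stable is that cluster under column resampling?
2. **Distance thresholds** — at which divergence cutoff does
   single-linkage clustering best reproduce the morphospecies, and how
   many species get erroneously *lumped* (merged with a neighbour) or
   *split* (scattered over several clusters)?
3. **Anomaly flagging** — species whose maximum intraspecific distance
   reaches their nearest-neighbour distance, exceeds ~2%, or whose
   nearest neighbour sits closer than ~2%, are queued for morphological
   reassessment; the dataset is then relabeled and re-analysed
   iteratively.

`barcodegap` implements this workflow end to end for aligned COI
matrices, with a seeded synthetic-data generator so each stage is
testable without any sequence download.

## The model and its pieces

### Distances

All distances use **pairwise deletion**: a column contributes to a pair
only when both sequences carry an unambiguous base (A/C/G/T) there.
Gaps, Ns, and all other IUPAC ambiguity codes count as missing — one
consistent rule across QC, composition, haplotype collapsing, and
distances, which keeps sequences with patchy coverage comparable.  The
default metric is the Kimura 2-parameter (K2P) distance

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q), $$

with $P$ and $Q$ the transition and transversion proportions over the
$n$ comparable sites.  When a logarithm argument is non-positive
(saturation) the distance is reported as undefined (`NA`) rather than
clamped: silently clamping would corrupt nearest-neighbour minima, which
are the workhorse statistic here.  p-distances are available for
comparison; at barcode-scale divergences the two give nearly identical
results.

### Quality control

A sequence passes QC when its sequenced length (non-gap columns,
including Ns) is at least 600 bp and its missing fraction (Ns plus
ambiguity codes, over that same length) is below 1%.  The boundary is
inclusive on length (600 passes) and exclusive on the missing fraction.
Each sequence is also translated in the three forward frames under the
invertebrate mitochondrial code; the frame minimising stop codons is
reported (ties to the lowest frame) and residual stops flag a likely
pseudogene or frame problem.  Codons containing missing bases translate
as unknown, never as stops.  The reading frame is auto-detected rather
than assumed, since barcode amplicons are not guaranteed to start
in-frame.

### Haplotypes

Haplotypes are the connected components of the *zero-distance graph*
within each species, not exact string-equality classes, so a sequence
with a terminal N run does not artificially split a haplotype it
matches everywhere it was scored.

### Species summaries and flags

For each species: the maximum and mean intraspecific distance (over all
within-species pairs; undefined for singletons) and the
nearest-neighbour minimum (over pairs against every other species).
Singletons are excluded from intraspecific statistics but *included* as
potential nearest neighbours.  Three flags drive reassessment, with
2% defaults on both cutoffs:

* `OVERLAP` — max intra ≥ min inter.  Deliberately inclusive (`>=`):
  flagging an exact tie for human review is cheap; missing one is not.
* `HIGH_INTRA` — max intra strictly above the cutoff (possible cryptic
  split, misidentification, or pseudogene).
* `LOW_INTER` — nearest neighbour strictly below the cutoff (possible
  lumping, introgression, or shared haplotypes).

### Trees, bootstrap, monophyly

The NJ implementation follows the Saitou–Nei agglomeration with the
Studier–Keppler criterion and three reproducibility rules: taxa are
sorted lexicographically first, criterion ties break toward the lowest
index pair, and a negative branch length is zeroed with the deficit
moved to its sister branch so path lengths are preserved.  These rules
make trees bit-identical across runs and input orderings, which matters
because bootstrap support values are compared against a 95% bar.

Monophyly is defined on the *unrooted* tree: a species is monophyletic
when some edge bipartition isolates exactly its specimens.  No outgroup
is available or assumed.  The paraphyly/polyphyly distinction requires a
root, so it is collapsed into "non-monophyletic" plus the number of
maximal all-conspecific clades, counted after rooting on the longest
edge (a neutral, deterministic rooting choice).

Bootstrap support for a species is the fraction of column-resampled
replicates whose NJ tree contains that species' exact bipartition.
Replicates with undefined distances are dropped and counted; more than
10% dropped aborts the run, since support values from a heavily censored
replicate set would not be comparable.  Each replicate runs on an RNG
substream derived from `(seed, replicate)`, so results are independent
of evaluation order.  Per-species bipartition frequency is reported
directly; no majority-rule consensus tree is built, as the frequency is
the quantity the 95% bar applies to.

### Threshold sweep

Single-linkage clusters at threshold $t$ link pairs with $d \le t$
(inclusive, so identical haplotypes merge even at $t = 0$).  Sweeping
$t$ from 0.1% to 3.0% in 0.1% steps scores each species as lumped,
split (a species can be both), or perfect; the identification success
rate is the percentage of perfect species and the optimal threshold is
the success argmax (ties toward the smallest $t$ — the stricter rule).
A species both lumped and split counts once in the error union.
Richness estimation gets its own optimum: the $t$ whose cluster count is
closest to the true species count, which typically sits slightly above
the identification optimum because lumping and splitting errors offset
in the count.  Singletons are scored by default (perfect iff alone in
their cluster); `min_n = 2` restricts scoring to multi-specimen
species, since published success rates are reported against both
denominators.

### Reassessment bookkeeping

Relabelings are *data*, never in-place edits: an ordered change set of
`RENAME` / `SPLIT` / `LUMP` / `EXCLUDE` records (TSV-serialisable, each
validated against the current table and audited with the affected
specimen ids) is applied to produce a new specimen table, and the
pre/post comparison table recomputes both summary sets from the same
distance matrix.  `RENAME` moves a whole label onto a fresh name — or,
with an explicit specimen list, moves individual misidentified
specimens onto an existing species; renaming an entire label onto an
existing one is refused and redirected to `LUMP`, which states the
intent.  `EXCLUDE` covers material deferred from analysis (e.g. a genus
whose species limits are unusable pending revision).

### Unknown assignment

Specimens labeled `UNKNOWN` (e.g. females that cannot be determined
morphologically) are assigned to the species of their nearest labeled
neighbour *only if* their single-linkage cluster at the chosen
threshold contains labeled members of exactly that species; an unknown
in a mixed cluster is `AMBIGUOUS`.  Bare nearest-neighbour matching
would silently mis-assign members of haplotype-sharing species pairs;
the cluster-exclusivity condition is what catches those.

### Locality test and sampling regression

Two auxiliary checks on intraspecific maxima: a one-tailed permutation
test of whether adding non-focal material raises the maximum
intraspecific distance (statistic: mean over species of
`max_all − max_local`; null built by re-drawing which specimens count
as non-focal, per species and permutation; add-one smoothing
`p = (1 + #{perm ≥ obs})/(1 + n_perm)` avoids p = 0), and an OLS
regression of maximum intraspecific distance on specimen count,
restricted to one region so sampling depth is not confounded with
geography.  The permutation statistic could equally have been a
per-species signed test; the mean difference was chosen as the simplest
statistic consistent with a one-tailed "does it increase" question, and
is documented as such.  Stability across permutation runs is assessed
by re-running with different seeds rather than by any internal
iteration scheme.

## The synthetic-data generator

`simulate_barcodes()` emulates the structure of a well-populated
northern-fauna barcode survey.  Choices, made once:

* **Species counts**: default 40 species; each is a singleton with
  probability 0.15, else carries `2 + Poisson(5)` specimens — matching
  a survey averaging ~7 specimens/species with ~15% singletons at a
  desk-scale species count.
* **Substitution process**: a two-rate Kimura-type model with exact
  closed-form site transition probabilities, κ = 6 (observed
  transition:transversion count ratio ≈ 3, typical of insect COI), and
  an AT-rich root composition (~69% A+T).  No indels are generated: the
  analysis alignment is fixed-length and the distance model is K2P, so
  gaps would only enter as missing data, which is planted separately.
* **Interspecific structure**: a random coalescent species tree whose
  node-depth *ranks* are mapped uniformly onto the target divergence
  range (default 0.8–11%).  Raw coalescent depths bunch near the
  present, which would drive every nearest-neighbour distance to the
  floor; rank mapping keeps a valid ultrametric tree while spreading
  split depths — realised nearest-neighbour distances then range from
  ~0.8% up to several percent with a mean near 4%.
* **Intraspecific structure**: individuals evolve from their species
  ancestor on exponential terminal branches with mean pairwise
  divergence 0.2% and a cap near 3%.
* **Missing data**: terminal N runs (20–80 bp) planted per specimen
  with a configurable rate, mimicking short reads that trip the
  600 bp / 1% N filters.
* **Anomalies**: `label_swap` (misidentification → `OVERLAP` on the
  recipient plus non-monophyly), `cryptic_split` (one label over two
  ancestors at divergence `d_c`, default 4% → `HIGH_INTRA`), and
  `shared_haplotype` (two labels over one gene pool → nearest-neighbour
  distance 0, `LOW_INTER`, mixed cluster).  Every planted anomaly is
  recorded with the flag it must trigger, so recovery is checkable
  against ground truth.
* Targets are calibrated through expected substitutions per site;
  exact hitting is not promised.  Realised mean intraspecific
  divergence tracks its target within ~30% relative error when
  averaged over species and seeds.

What the generator does *not* emulate: coalescent gene-tree/species-tree
discordance, recombination, codon-aware rate variation, pseudogenes,
or geographic population structure (regions are labels, not demes).
Passing tests therefore demonstrate that the *pipeline machinery* is
correct under controlled conditions — not that real data meet those
conditions.

## Numerical and degenerate-input choices

* Distances are held as proportions internally; every user-facing table
  reports percent (rounded to 2 decimals only on output).
* Histogram bins are half-open `[kw, (k+1)w)`; a boundary value falls
  in the upper bin.
* Undefined distances never abort a matrix: pairs are flagged `NA`,
  excluded from summaries with a warning, treated as above any
  threshold in clustering, and refused (with instructions) by NJ,
  which cannot proceed without a complete matrix.
* An alignment whose sequences all fail QC yields an empty alignment
  plus a warning, not silence.
* Internal coordinates are 0-based half-open; reported columns and
  frames are 1-based.

## Problem sizes

The shipped tests and the acceptance script run on generated data at
the generator's default scale (40 species, ~260 specimens, 658 bp),
with 200 bootstrap replicates in the acceptance run and scaled-down
replicate counts (e.g. `n_perm = 200` over 200 simulated datasets for
the permutation-calibration check) in the property tests.  These sizes
were chosen so the whole suite exercises every stage end to end in
minutes on a single core; all counts are parameters, and nothing in the
implementation assumes them.

## Known limitations

* Monophyly counts depend mildly on the longest-edge rooting when a
  species is non-monophyletic; the monophyletic/non-monophyletic verdict
  itself is rooting-free.
* Bootstrap support is per-species bipartition frequency, which is
  conservative relative to relaxed cluster definitions that tolerate a
  few intruding tips.
* The threshold sweep assumes the morphospecies labels are the truth
  being recovered; it measures correspondence, not correctness.
* NJ is O(n³) in pure R; matrices beyond a few thousand specimens are
  outside the intended scale.
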