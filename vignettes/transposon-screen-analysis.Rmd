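---
title: "Modelling mutagenesis and selection in transposon screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mutagenesis and selection in transposon screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciscall)
```

## The problem

Forward genetic screens with Sleeping Beauty (SB) or PiggyBac (PB)
transposons generate tumours whose genomes carry dozens of transposon
insertions each. Regions hit more often across independent tumours than
expected by chance — common insertion sites (CIS) — are candidates for
positively selected cancer drivers. The catch is that "expected by chance"
is far from uniform: SB integrates only at TA dinucleotides and PB at TTAA
tetranucleotides, and within those motif universes both transposases prefer
particular sequence contexts, transcribed regions, and open chromatin.
A CIS caller that ignores these preferences mistakes insertion-hungry
neutral regions for selected ones.

ciscall separates the two forces explicitly:

1. a **mutagenesis model** estimates the neutral insertion rate of every
   motif site from genomic and epigenomic features, and
2. a **selection model** tests whether a region's observed insertion count
   exceeds its aggregated neutral expectation.

## The mutagenesis model

A random-forest classifier is trained to discriminate observed insertion
sites (all samples pooled, deduplicated to unique genomic sites; read
coverage is deliberately discarded) from an equal number of motif sites
drawn uniformly at random from the analysis chromosomes. Writing
$\hat y_m$ for the classifier's probability that site $m$ is an observed
site within this balanced training universe, the balanced odds
$\hat\omega_m = \hat y_m / (1 - \hat y_m)$ are rescaled to genome-scale
odds by the calibration constant

$$f_0 = \frac{\#\text{negatives in training}}{\#\text{motif sites in the genome}},$$

and converted to a per-site Poisson rate

$$\lambda_m = \log\!\left(1 + \hat\omega_m f_0\right),$$

so that the probability of seeing at least one insertion at site $m$ is
$1 - e^{-\lambda_m} = \hat\omega_m f_0 / (1 + \hat\omega_m f_0)$. Poisson
additivity then gives the neutral rate of any region $j$ as
$\Lambda_j = \sum_{m \in j} \lambda_m$, summed over motif sites whose start
lies in the region. The identity between the rate and probability
parameterizations is enforced to machine precision in the test suite; it is
an algebraic property of the transform, not an approximation.

### Features

Each motif site is described by:

* one-hot encoded sequence in a fixed window of 10 bp + motif + 10 bp
  (22 columns for TA, 24 for TTAA), anchored at the motif start — the
  invariant motif columns carry no information and are ignored by the
  forest; window positions beyond a chromosome end are all-zero blocks;
* unsigned bp distances to the nearest transcription start site,
  transcription termination site, gene body (0 for intragenic sites),
  DNase-seq peak and ATAC-seq peak (0 on overlap). Peaks are q-value
  filtered (< 0.05) when the file carries a q-value column and merged.

Distances are unsigned because the model consumes proximity, not
orientation; signed profiles are a descriptive device and available through
`fold_enrichment_profile()`.

### Training protocol

The balanced data are split 90 % / 10 % (configurable `test_fraction`); six
random-forest hyperparameters (number of trees, `mtry`, minimum node size,
maximum depth, bootstrap flag, sample fraction) are chosen by randomized
search (default 100 draws) with 5-fold cross-validation inside the training
split, optimizing the area under the ROC curve; AUC is our choice of search
metric and is recorded in the training metadata. The final forest is
refitted on the full training split and its held-out AUC reported. A fast
profile (budget 10, 3 folds) is exposed for desk-scale work and used by the
package's own simulations. All randomness — negative draw, split, folds,
forests — is governed by one integer seed, and retraining with the same
seed reproduces the selected hyperparameters and predictions exactly.

Negative (control) sites exclude the observed insertion sites and are drawn
from the same chromosome universe as the positives (donor and sex
chromosomes removed), so that labels are clean and the two classes differ
only by insertion status. Classifier probabilities are clipped to
$[10^{-6}, 1 - 10^{-6}]$ before the odds transform to keep rates finite.

## The selection model

Insertions are counted per sample $i$ and region $j$ as **unique
per-sample sites**; duplicate records of one site in one sample count once.
Counts are modelled as Poisson in two stages.

**Stage 1 — global factors.** The genome is tiled into 50-kb bins and

$$\log E_{ij} = \log\sigma_i + \log\chi_{k(j)} + \log\Lambda_j$$

is fitted by a Poisson GLM (log link, `stats::glm`, deviance tolerance
$10^{-8}$, 100 iterations), with $\sigma_i$ a per-sample sequencing-depth
factor, $\chi_k$ a per-chromosome factor, and $\log\Lambda_j$ a fixed
offset. Bins with $\Lambda_j = 0$ are dropped. Only the product surface
$\sigma_i\chi_k$ is identifiable (any constant can move between the
factors), so downstream computations use the fitted products; the
individual factors are reported with the first sample and first chromosome
normalized to 1 for display. The GLM score equations force the fitted
per-sample and per-chromosome totals to match the observed totals exactly —
a property the tests verify.

**Stage 2 — per-region selection.** With the products fixed, each region
gets its own intercept:

$$\log E_{ij} = \beta_j + \log\sigma_i + \log\chi_{k(j)} + \log\Lambda_j.$$

An intercept-only Poisson GLM with fixed offsets has a closed-form MLE,

$$\hat\beta_j = \log\frac{K_j}{S_j}, \qquad K_j = \sum_i k_{ij}, \quad
S_j = \Lambda_j \sum_i \sigma_i \chi_{k(j)},$$

with standard error $1/\sqrt{K_j}$ from the observed Fisher information
(equal to the expected information at the MLE for this model). Regions with
$K_j = 0$ get $\hat\beta_j = -\infty$ and p-value 1. The closed form is
cross-checked against iterative GLM fitting in the tests; per-region fits
are independent of each other and of input record order.

$\beta_j > 0$ is tested one-sided with the Wald statistic
$z_j = \hat\beta_j / \mathrm{se}_j$ against the standard normal upper tail.
Regions are tested only if hit in at least
$\max(3, \lceil 0.05\,n_\text{samples}\rceil)$ tumours and if
$\Lambda_j > 0$; the family-wise error rate is controlled at 5 % by
Bonferroni correction with $m$ equal to the number of *tested* regions
(recorded in the run metadata — an alternative reading would correct over
all annotated regions, which is strictly more conservative).

**Null mode.** Setting every per-site rate to a constant reduces
$\Lambda_j$ to (a multiple of) the motif count of region $j$; the
global-factor stage absorbs the constant, so results are exactly those of a
motif-count-only background. This is the built-in ablation for judging what
the mutagenesis model adds.

## Regions

Targets can be genes (merged span of all transcripts sharing a gene id —
the simplest deterministic reading of a gene annotation), fixed windows of
any size (non-overlapping tiles, last partial tile kept), or a custom GTF.
A site inside two overlapping regions counts toward both: regions are
tested marginally, so no arbitrary assignment is needed. No promoter
extension is applied by default. Regions without motif sites are reported
but untested.

## Data preparation

Mapped insertion positions are snapped to the nearest indexed motif start
within 5 bp (mapping artifacts shift a few nucleotides; ties break to the
leftmost motif for determinism; records with no motif in range are dropped
and counted rather than guessed). Insertions on the donor chromosome
(local hopping) and on sex chromosomes (variable copy number) are excluded.
Coordinates are 1-based closed throughout the package — the R/Bioconductor
convention — with GTF read natively and BED converted on read; insertion
tables may declare 0-based positions via a flag rather than the reader
guessing.

Because TA and TTAA are reverse-complement palindromes, a forward-strand
scan indexes every double-stranded motif occurrence; a non-palindromic
motif would require scanning both strands.

## The synthetic screens

`sim_config()` / `simulate_genome()` / `simulate_screen()` generate fully
self-contained screens: uniform-composition random chromosomes,
non-overlapping genes, per-assay accessibility peaks, a neutral rate field
$\lambda_m \propto \exp(w \cdot x_m)$ driven by the same features the
classifier sees (intragenic indicator, in-peak indicators, exponential
TSS-proximity with 10-kb decay), per-sample depth factors, per-chromosome
factors, and optional planted selection coefficients multiplying the rate
inside chosen genes. Sampling is presence/absence per site and sample
(an event count is Poisson; the site is emitted if at least one event
occurred), matching the unique-site contract of the real pipeline. Default
desk scale is 2 chromosomes × 1 Mb, 100 genes, 10 samples with a four-fold
depth spread, 2000 expected insertions per sample — a full two-step run in
minutes on one CPU. The package's own checks use smaller calibration
genomes (2 × 300 kb and 2 × 500 kb, 150–250 insertions per sample) so that
hundreds of replicate screens stay cheap.

What the generator deliberately does **not** emulate: realistic genome
composition (GC structure, repeats), transcription-coupled sequence biases
beyond the configured features, local hopping around a donor locus, and
read-count noise models. Passing tests therefore demonstrate correctness of
the estimator and calibration under the model's own assumptions, not
performance on any particular real screen.

## Numerical and design notes

* Probability clipping at $10^{-6}$ bounds $\hat\omega$; `log1p` is used
  for $\lambda$ to keep precision at tiny rates.
* Snapping ties break leftmost; window region ids are `chrom:start-end`;
  all tabulations are sorted and deterministic.
* Per-site presence sampling saturates at high per-site rates
  ($E[\text{unique sites}] = \sum_m (1 - e^{-\mu_m}) < \sum_m \mu_m$), so
  $\hat\beta$ acquires a small negative bias when individual sites approach
  rate 1 — negligible in the sparse regime of real screens and of the
  package defaults.
* Stage 1 estimates $\sigma$ and $\chi$ from all bins, including selected
  ones; if selected regions carry a large share of a chromosome's counts
  (possible in toy genomes, not in genome-scale screens), the chromosome
  factor absorbs part of the selection signal and attenuates $\hat\beta$.
  The simulations used by the package's checks therefore keep planted
  counts a small fraction of each chromosome's total. At genome scale this
  contamination is negligible; a robust-fitting variant (excluding
  candidate regions from stage 1) would be the extension if it were not.
* A sample with zero insertions drives its $\sigma_i$ to zero with a
  warning rather than an error; the GLM remains well defined for the rest.
* The search metric for hyperparameters (AUC) and the Bonferroni universe
  ($m$ = tested regions) are both recorded in output metadata, since either
  could defensibly be chosen otherwise.

## Limitations

* Poisson counts with fixed offsets ignore stage-1 estimation noise and
  any extra-Poisson variation; with very few tumours the Wald test's normal
  approximation is optimistic for small $K_j$. The tumour-count filter
  removes the worst-supported regions before testing.
* Local hopping is handled by exclusion, not modelling: the donor
  chromosome is simply removed, and within-chromosome position effects
  beyond the global factor are not captured.
* The mutagenesis model is only as good as its features; chromatin tracks
  from a different cell type than the screen's tumour type shift the
  background accordingly. Users can retrain on their own peak files.
* The sequence window (±10 bp) and the five distance features are fixed
  schema; adding feature classes requires retraining with a new schema (the
  model archive stores a schema fingerprint and refuses mismatched
  genomes).
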