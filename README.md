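# ciscall

Common insertion site (CIS) detection for Sleeping Beauty (SB) and PiggyBac
(PB) transposon insertional mutagenesis screens.

Transposon screens identify cancer drivers by selection: regions hit by
insertions in more independent tumours than chance allows. But "chance" is
biased — SB integrates only at TA dinucleotides, PB at TTAA motifs, and both
further prefer particular sequence contexts, genic regions and open
chromatin. ciscall is for researchers analysing such screens who want the
neutral insertion landscape modelled explicitly instead of assumed uniform.

## Method

The analysis has two steps.

**1. Mutagenesis model** — a random-forest classifier discriminates
observed insertion sites from an equal number of random motif sites, using
±10 bp sequence context and distances to the nearest TSS, TTS, gene body,
DNase-seq peak and ATAC-seq peak. Its calibrated probability for site *m*
becomes a neutral Poisson rate

&nbsp;&nbsp;&nbsp;&nbsp;λ<sub>m</sub> = log(1 + ω̂<sub>m</sub>·f₀),
&nbsp; ω̂<sub>m</sub> = ŷ<sub>m</sub>/(1 − ŷ<sub>m</sub>),
&nbsp; f₀ = n<sub>neg</sub> / n<sub>motif sites</sub>,

and region *j*'s neutral rate is Λ<sub>j</sub> = Σ<sub>m∈j</sub> λ<sub>m</sub>.

**2. Selection model** — per-sample, per-region unique-insertion counts
k<sub>ij</sub> are Poisson with

&nbsp;&nbsp;&nbsp;&nbsp;log E<sub>ij</sub> = β<sub>j</sub> + log σ<sub>i</sub> + log χ<sub>k</sub> + log Λ<sub>j</sub>,

where σ<sub>i</sub> (sequencing depth) and χ<sub>k</sub> (chromosome
effects) are fitted first on 50-kb bins, then each region's selection
coefficient β<sub>j</sub> is estimated with those factors fixed as offsets
(closed form: β̂<sub>j</sub> = log K<sub>j</sub>/S<sub>j</sub>, se =
1/√K<sub>j</sub>). Regions hit in at least max(3, ⌈5% of tumours⌉) samples
are tested one-sided for β<sub>j</sub> > 0 (Wald), with Bonferroni control
of the family-wise error rate at 5%. A *null mode* replaces Λ<sub>j</sub>
by the region's motif count, isolating what the mutagenesis model adds.

The package also ships a complete synthetic-screen generator (genome,
annotation, peaks, biased rate field, depth/chromosome factors, planted
selection), diagnostics (sequence logos, fold-enrichment profiles,
precision curves, Jaccard agreement) and a command-line interface
(`exec/ciscall`, subcommands `simulate`, `fit-mutagenesis`, `call-cis`,
`diagnose`).

## Worked example

A synthetic SB screen with two genes planted under five-fold selection
(β = log 5 ≈ 1.609):

```r
library(ciscall)

cfg <- sim_config(seed = 42, n_chroms = 2, chrom_length = 3e5, n_genes = 40,
                  gene_length = c(3000, 8000), insertions_per_sample = 150,
                  selected_regions = data.frame(
                    region_id = c("gene_chr1_001", "gene_chr2_005"),
                    beta = log(5)))
sim    <- simulate_genome(cfg)
screen <- simulate_screen(sim, seed = 7, shift_prob = 0.2)
ins    <- preprocess_insertions(screen, sim$index)
fit    <- call_cis(ins, sim$regions, sim$true_rates,
                   lengths = chrom_lengths(sim$genome), mode = "mutagenesis")
summary(fit)
```

```
Common insertion site fit (mutagenesis background)
  40 regions, 40 tested (tumour-count filter), 2 significant at FWER 0.05 (Bonferroni, one-sided Wald)
  10 samples, 1277 region-assigned insertions

Significant regions:
     region_id chrom total_insertions n_samples_hit  beta    se    pvalue
 gene_chr2_005  chr2              262            10 1.389 0.062 2.64e-112
 gene_chr1_001  chr1              205            10 1.436 0.070  3.09e-94
      padj
 1.05e-110
  1.24e-92
```

Exactly the two planted genes are recovered; their estimated selection
coefficients (1.39 and 1.44; fold-enrichments e^β ≈ 4.0 and 4.2) sit close
to the simulated log 5, with the small shortfall expected from unique-site
saturation. `coef(fit)` returns the β̂ vector, `predict(fit)` the fitted
expected counts, `residuals(fit)` Pearson residuals, `simulate(fit)`
parametric-bootstrap count matrices, and `plot(fit)` a Manhattan-style
overview. Of the 2008 raw records in this example, 370 had jittered
positions and were snapped back to their motif (`attr(ins, "snap_report")`).

To retrain the background on your own screen instead of using true rates:

```r
model <- fit_mutagenesis(ins, sim$genome, sim$annotation, sim$index,
                         search_budget = 10, cv_folds = 3, seed = 1)
rates <- predict_site_rates(model, sim$index, sim$genome, sim$annotation)
fit   <- call_cis(ins, sim$regions, rates,
                  lengths = chrom_lengths(sim$genome))
```

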