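# intromodal

Intron retention, expression bimodality and bet-hedging fitness analysis
for budding yeast.

## The problem

Osmotic stress (LiCl, NaCl, high glucose) makes *Saccharomyces cerevisiae*
retain introns, and the effect concentrates on ribosomal-protein (RP)
transcripts. For a duplicated RP gene whose copy carries a 5′ UTR intron
(the *RPS22A*/*RPS22B* pair is the canonical case), retention can split an
isogenic population into stable high- and low-expressing subpopulations —
a bimodal single-cell fluorescence histogram — and the subpopulations
survive starvation differently: a bet-hedging strategy. `intromodal` is for
researchers who want to quantify each link of that chain: how much retention
a condition induces, whether retention concentrates on a gene set, how
bimodal a reporter's expression is across a two-drug gradient, and whether
sorted subpopulations differ in growth and survival.

## What it computes

**Intron retention.** From feature-level read counts, the density estimator

    r = (I / L_I) / (C / L_C)

(intron read density over CDS read density; CDS introns jointly, 5′ UTR
introns separately), and a junction variant
`r_J = (((n5 + n3)/2) / read_length) / (C / L_C)` using only contiguous
reads that span the intron boundaries. Fold changes versus a no-drug
control feed a ranked gene list tested for gene-set enrichment with an
exact hypergeometric tail and Benjamini–Hochberg correction.

**Bimodality.** Cell-wise FITC-H/FSC-H normalization, 100 log-spaced
histogram bins over [1e-3, 1e5], and the trough depth `d`: the y-axis
distance between the trough and the lower of the two flanking peaks
(the prominence of the inverted-histogram peak). Pooled over a gradient
grid, the running average of `d` against median expression `m` locates the
median of maximal bimodality.

**Growth and design.** Log-linear OD fitting in a fixed window, a 0.85/h
contamination filter, IC interpolation and antiparallel isogrowth gradient
design.

**Resampling tests.** The colony-count statistic Δ (total low-expression
minus total high-expression colonies) tested against 10⁴ Poisson surrogates
with per-timepoint pooled rates, plus permutation, Mann–Whitney (exact
enumeration at small n) and pooled-variance t tests.

**Synthetic data.** Seeded generators with recorded ground truth for every
input: reads from spliced/retained isoform mixtures, two-component
log-normal flow-cytometry grids, Poisson colony counts, logistic OD curves.

## Worked example

```r
library(intromodal)

models <- gen_gene_models(20, frac_rp = 0.25, frac_utr_intron = 0.5, seed = 1)
control <- sim_truth(models, rho_utr = 0.02, rho_cds = 0.02)
treated <- sim_truth(models, rho_utr = 0.30, rho_cds = 0.30)
reads_t <- sim_reads(models, treated, depth = 200, seed = 2)
counts_t <- count_features(reads_t, models, read_length = 50)
counts_t
#> <feature_counts> 20 genes, 24 introns (8 five_prime_utr, 16 cds)
#>   CDS reads: 2049 total; intron reads: 700 total; read length 50 bp; 0 read(s) ignored

rt <- retention_table(counts_t, method = "density")
head(rt, 3)
#>   gene_id   intron_class intron  method         r undefined
#> 1    g001 five_prime_utr      1 density 0.2247299     FALSE
#> 2    g002 five_prime_utr      1 density 0.2117395     FALSE
#> 3    g003            cds     NA density 0.3020586     FALSE
```

Per-gene rates land near the simulated truth of 0.30: each `r` is the
intron/CDS read-density ratio, i.e. the estimated fraction of transcripts
retaining the intron. Folds versus a control run then rank genes
(`normalize_to_control()`, `rank_by_fold()`), and
`hypergeom_enrichment()` tests whether RP-labeled genes crowd the top.

For a survival comparison:

```r
cfu <- sim_survival(rate_low = 0.05, rate_high = 0.5, cfu0 = 200, seed = 3)
poisson_bootstrap_p(cfu, n_surrogates = 10000, seed = 4)
#>  Poisson-surrogate bootstrap (10000 surrogates, pooled per-timepoint rates)
#>
#> data:  colony counts by population, timepoint and replicate
#> Delta = 648, p-value = 9.999e-05
#> alternative hypothesis: two.sided
```

Δ = 648 more colonies from the slow-dying population across all
timepoints; no surrogate from the pooled-rate null reached it, so the
reported two-sided p value sits at the add-one floor 1/(n+1).

`run_scenario(analysis_config(seed = 1), "all", out_dir = "run1")`
executes the three end-to-end scenarios (retention → enrichment, gradient →
bimodality map, survival → bootstrap) into a reproducible run directory.

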