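---
title: "Methods: estimators, scores and simulation design in intromodal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, scores and simulation design in intromodal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biology in one paragraph

Osmotic stress (e.g. LiCl) makes budding yeast retain introns, and the effect
concentrates on ribosomal-protein (RP) transcripts. For a duplicated RP gene
whose copy carries a 5' UTR intron, retention can split an isogenic
population into stable high- and low-expressing subpopulations — visible as
a bimodal single-cell fluorescence histogram — and the two subpopulations
fare differently under starvation, the signature of a bet-hedging strategy.
`intromodal` implements the quantitative machinery needed to study this
chain: intron-retention estimation from RNA-seq read counts, a
non-parametric bimodality score over two-drug gradients, growth-rate and
isobole utilities, and the resampling tests for survival and fitness
comparisons. Every stage is paired with a seeded generator that simulates
its input with known ground truth, so the whole pipeline is testable on a
laptop without sequencing or cytometry data.

# Intron retention

## Estimators

For a gene with intron read count $I$ over intron length $L_I$ and CDS read
count $C$ over exonic-CDS length $L_C$, the **density estimator** is

$$ r = \frac{I / L_I}{C / L_C}. $$

Genes with several CDS introns are scored jointly ($I = \sum I_k$,
$L_I = \sum L_{I,k}$); each 5' UTR intron is scored on its own. The
**junction estimator** replaces the numerator with boundary-crossing
contiguous reads: with $n_5$ and $n_3$ single-block reads strictly spanning
the 5' and 3' intron ends and read length $\ell$ (default 50 bp),

$$ r_J = \frac{(n_5 + n_3)/2 \,/\, \ell}{C / L_C}. $$

Both are ratios of read densities and estimate the fraction of transcripts
retaining the intron. Counting rules: a read increments a feature when any
aligned block overlaps it by at least 1 bp; intron and CDS counters are
independent (one read may increment both); a gapped read whose gap spans the
intron never counts toward it; junction-end counting requires at least one
base on each side of the boundary, so a read merely touching the boundary is
uninformative and not counted. Genes with $C = 0$ yield a flagged undefined
record and are excluded from ranking rather than imputed.

## Fold changes, ranking, enrichment

Treated records are matched to the no-drug control by gene, intron class,
intron index and method, and the fold change is
$(r_t + \varepsilon)/(r_c + \varepsilon)$ with pseudocount
$\varepsilon = 10^{-3} \times$ (median nonzero rate pooled over both
conditions) unless supplied — zero-count control introns otherwise give
undefined folds. Genes contribute their maximum fold across records (a gene
rank should reflect its strongest intron signal), descending order, ties
broken lexicographically for determinism. Enrichment of a gene set in the
top $n$ of the ranked list (default: top decile) is the exact hypergeometric
upper tail, Benjamini–Hochberg-adjusted across sets. A fixed-cutoff
hypergeometric test is used rather than a threshold-free ranked-list
statistic: the cutoff is exposed as a parameter, and the fixed-cutoff form
has an exact, dependency-free null.

## Numerical behaviour of the density estimator

Block-overlap counting inflates every feature's expected count from
$\lambda L$ to $\lambda (L + \ell - 1)$: reads starting up to $\ell - 1$ bp
upstream still overlap. In the ratio this inflation cancels only when intron
and CDS lengths are comparable. Two consequences shape the toy-genome
defaults and the recovery study:

* `gen_gene_models()` draws intron and CDS lengths from the same range
  (300–600 bp) — deliberately RP-like, since yeast RP introns are unusually
  long, often comparable to their short CDS. With both lengths from one
  distribution the edge factors cancel in expectation and the estimator's
  residual bias is below 0.01 at full retention.
* A CDS **split by a CDS intron** is counted as two chunks and collects the
  edge inflation twice ($\approx 2(\ell-1)/L_C$ relative), deflating the
  retention ratio of short toy genes by up to ~10%. This is inherent to
  block-overlap counting of interrupted features (the standard
  feature-counting convention), not an implementation artifact. The
  retention-recovery experiment therefore uses genes with a single 5' UTR
  intron, whose host CDS is uninterrupted.

At the recovery study's depth (~250 expected intron reads per intron at full
retention) a single per-gene estimate carries a Poisson noise floor of
$\sigma \approx 0.09$ at $\rho = 1$; the experiment's unit of evaluation is
therefore the per-simulation estimate (mean over the 20 genes of one seeded
dataset), i.e. what one simulated experiment reports. Bias and RMSE are
taken over 20 such replicates per $\rho \in \{0, 0.1, \dots, 1\}$.

# Bimodality over drug gradients

Per well, green fluorescence is normalized cell-wise by forward scatter
(FITC-H / FSC-H), removing cell-size variation; cells with non-positive
scatter are dropped and tallied. Normalized values are binned into 100
relative-frequency bins spaced logarithmically over $[10^{-3}, 10^5]$;
out-of-range values are excluded but counted, never silently clipped into
the edge bins. The **trough depth** $d$ is the y-axis distance between the
trough separating two histogram peaks and the *lower* of those peaks —
operationally, the prominence of the peak created by inverting the
histogram, maximized over candidate troughs (multiple troughs take the
maximum: the model expects two subpopulations and the maximum generalizes
gracefully). $d = 0$ exactly for unimodal or monotone histograms, and, by a
degenerate-input guard, for histograms with fewer than three nonzero bins.

Smoothing: a centered moving average over 5 bins (default) suppresses
single-bin noise troughs before peak finding; `smooth_window = 1` is the
raw definitional path and is what all oracle comparisons use. Moving-average
windows follow the plate-tool convention (`ceiling((w-1)/2)` points back,
`floor((w-1)/2)` forward, clipped at the edges; a window wider than the
series collapses to the global mean). The per-well summary is the pair
(median expression $m$, depth $d$); pooling all wells sorted by $m$ (ties
by well id) and smoothing $d$ with a running window of 30 points locates
$m_\text{peak}$, the median of maximal bimodality — the fingerprint of an
unstable fixed point between two stable expression states.

## What the flow simulator emulates — and what it does not

`sim_flow_grid()` draws each cell's expression from a two-component
log10-normal mixture (modes at $10^{-0.6}$ and $10^{0.6}$, common
$\sigma = 0.2$ log10 units). Drug doses set a target median through a
log-linearly declining dose response; the high-mode weight is
$p = \mathrm{logis}\!\left((\log_{10} m - \log_{10} m^*)/s\right)$ with
$m^* = 1$ and $s = 0.15$ — the simplest monotone map that makes bimodality
peak at an intermediate median, as a bistable circuit would. Forward scatter
is an independent log-normal (no size–expression coupling is assumed; the
ratio still exercises the normalization). Defaults: 24 × 24 wells, 10,000
cells per well (one cytometer acquisition); the recovery experiment runs
2,000 cells per well, which keeps the depth estimate's noise well below the
inter-well spacing while cutting runtime five-fold.

Limitations: the generator has no autofluorescence background, no
instrument gating, no cell-cycle or size–expression correlation, and a
parametric two-mode shape; passing tests therefore demonstrate that the
score recovers a known mixture structure, not that real cytometry artifacts
are handled. Note that near $p = 1/2$ the mixture median moves across the
trough region, so one dose step shifts the median far more than the dose
grid suggests; the recovery tolerance ("within one inter-well spacing") is
accordingly measured on the generating analytic medians, not on the dose
axis.

# Growth and isogrowth design

Growth rates are the slope of an ordinary least-squares line through
$\log(\mathrm{OD} - \mathrm{background})$ against time, restricted to a
log-linear window — (0.01, 1) for raw measurements, (0.02, 0.2) for
background-corrected ones. The default background estimate is the **mean**
of the first three readings: with realistic measurement noise (sd 0.002)
the minimum of three readings is biased low by about $1.7\times10^{-3}$,
which propagates to a ~0.01/h downward rate bias at the lower window edge,
while the mean is unbiased (the inoculum's contribution is negligible at
typical dilutions). Fitted rates above 0.85/h are flagged as bacterial
contamination and discarded (strict inequality: exactly 0.85 is kept). The
growth simulator is logistic with carrying capacity 1.8 (typical yeast
rich-medium saturation), background 0.08 and 20-minute sampling; with a
capacity near 1 the 0.02–0.2 window would already sit at 10–20% saturation
and the log-linear fit would under-read the exponential rate by ~0.03/h —
a property of the truth curve, not of the estimator.

Dose–response curves are made monotone by pool-adjacent-violators before
linear interpolation of inhibitory concentrations (noise can break
monotonicity; interpolation needs it). The antiparallel isogrowth gradient
mixes the two iso-effective doses linearly:
$(\mathrm{IC}_A (1 - t),\, \mathrm{IC}_B\, t)$ for $t$ on a uniform grid —
the simplest design that holds overall inhibition constant under Loewe
additivity; empirical fine-tuning of a robotic setup is out of scope.

# Resampling statistics

The survival statistic is $\Delta$ = total low-expression colonies minus
total high-expression colonies over all timepoints and replicates. Its null
distribution comes from Poisson surrogates: $\lambda_t$ is the mean colony
count at timepoint $t$ pooled over *both* populations (the
maximum-likelihood rate under the null of no difference), each surrogate
redraws every cell from $\mathrm{Poisson}(\lambda_t)$, and
$p = (\#\{\Delta^* \ge \Delta_{\mathrm{obs}}\} + 1)/(n + 1)$ (two-sided:
$|\Delta^*| \ge |\Delta_{\mathrm{obs}}|$). Design choices: pooling across
populations (the plain per-timepoint mean is the null MLE), the add-one
guard (avoids $p = 0$; standard resampling practice), `>=` in the tail
count, and both sidednesses always reported with two-sided as the default.
Default $10^4$ surrogates.

The permutation test for a difference in binary fractions exploits that,
with 0/1 outcomes, a label permutation's statistic depends only on how many
successes land in one group — so the permutation distribution is sampled
exactly by hypergeometric draws. The Mann–Whitney U test uses exact
enumeration of rank splits (with midrank tie credit) when $nm \le 400$ and
the number of splits is feasible (`choose(n+m, n)` ≤ 2×10^5; e.g.
$n = m = 14$ has $nm = 196$ but 40M splits and falls back), otherwise a
tie-corrected, continuity-corrected normal approximation. The t test is the
pooled-variance two-sample form with $n + m - 2$ degrees of freedom;
zero-pooled-variance inputs return the $p \in \{0, 1\}$ limits with a
degenerate flag instead of erroring.

# Synthetic data: scope of the guarantees

All generators are pure functions of (parameters, seed). The read simulator
draws per-isoform Poisson read counts with uniform start positions along the
isoform, splitting junction-crossing reads into blocks; it models no
sequencing errors, no multi-mapping, no strand and no fragment-length
distribution ("no mismatches" is represented structurally as the
single-block requirement). The survival generator is exponential decay with
Poisson plating noise; true per-condition retention fractions of the real
stress conditions are unknown, so the $\rho$ grids are stand-ins with known
truth, not calibrations to any particular drug.

# Orchestration and problem sizes

`analysis_config()` holds every constant (seed, 50 bp reads, histogram
layout, window sizes, $10^4$ surrogates, OD windows, 0.85/h cutoff, top
decile) and round-trips through YAML; `run_scenario()` executes
simulate→analyze scenarios into a run directory whose outputs are
byte-reproducible given the configuration (only the log carries
timestamps). The validation experiments use: 11 retention fractions × 20
seeds × 20 genes at depth 500 (≈250 expected intron reads per intron); 100
random counting instances up to 10^4 reads; 500 random histograms against
an exhaustive triple-scan oracle; 20 gradient grids of 24 × 24 wells ×
2,000 cells; 500 null datasets × 2,000 surrogates for calibration plus 100
runs × 10^4 surrogates for power; and 100 end-to-end enrichment runs of 60
genes against 5 decoy sets. These sizes were chosen so each recovery
quantity's Monte-Carlo error is several times smaller than the band it is
checked against.

# Known limitations

* Retention estimates on genes whose CDS is interrupted by CDS introns
  carry the structural edge deflation discussed above; at genome-realistic
  CDS lengths the effect shrinks as $2(\ell-1)/L_C$.
* The junction estimator has an intrinsic $(\ell-1)/\ell$ factor and
  inherits the CDS edge inflation, so it reads ~10% lower than the density
  estimator on short features; the two are rank-concordant, which is what
  downstream ranking uses.
* No BAM/CIGAR input in the core: reads enter as block-structured records
  (BED12-style TSV). An aligner adapter would sit behind the same contract.
* The bimodality score is non-parametric by design and reports no
  subpopulation parameters; fitting the mixture is out of scope.
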