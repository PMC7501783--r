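---
title: "Sample-size effects on split-migration demographic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-size effects on split-migration demographic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfsize)
```

## The question

How many individuals per population are enough to estimate demographic
parameters from SNP data?  `sfsize` implements a complete evaluation
pipeline for this question in the two-population *split-migration*
(isolation-with-migration) setting: simulate phased, one-SNP-per-locus
datasets with known demography; fit the model to the joint
site-frequency spectrum (SFS) by Poisson random-field composite
likelihood; subsample individuals symmetrically down to 1:1; and
summarize the loss of accuracy by the scaled root mean square error
(SRMSE) and its linear regression on sample size.  The package also
ships a published benchmark table of SRMSE values for eight diverging
bird lineages (UCE SNP panels of 1,636–2,656 variable loci, 6–8 diploid
individuals per population) and reproduces its regression summaries
exactly.

## The model and its units

An ancestral population of effective size $N_{ref}$ splits at time $T$
into two populations of constant relative sizes $\nu_1$ and $\nu_2$
(units of $N_{ref}$), exchanging migrants symmetrically so that each
lineage migrates at rate $m/2$ per unit coalescent time.  Time is
measured in $2N_{ref}$ generations.  The fifth parameter,
$\Theta = 4 N_{ref}\mu$ aggregated over loci, enters the likelihood as
a pure scale and is profiled out analytically.

The data summary is the joint SFS: cell $(i, j)$ counts loci whose
derived allele appears $i$ times among the $2n_1$ population-1
haplotypes and $j$ times among the $2n_2$ population-2 haplotypes.  The
composite likelihood treats unmasked cells as independent Poisson
counts $S_{ij} \sim \mathrm{Pois}(\theta M_{ij})$ with $M$ the expected
spectrum at $\Theta = 1$:

$$\ell(\nu_1,\nu_2,T,m,\theta) = \sum_{ij}
  S_{ij}\log(\theta M_{ij}) - \theta M_{ij} - \log\Gamma(S_{ij}+1),
  \qquad \hat\theta = \frac{\sum S_{ij}}{\sum M_{ij}}.$$

## The expectation engine

$M$ is computed by Monte Carlo branch-length averaging over
structured-coalescent genealogies: $M_{ij} = \tfrac12 E[\ell_{ij}]$,
where $\ell_{ij}$ is the total branch length subtending exactly $i$
population-1 and $j$ population-2 haplotypes, averaged over $R$
genealogies simulated backward in time (two demes with pairwise
coalescence rate $1/\nu_k$ and per-lineage migration $m/2$ until $T$,
one ancestral deme of size 1 beyond).  This engine is an intentional
replacement for the diffusion-approximation solvers usually used for
this model: it is exactly testable against coalescent closed forms
(in the panmictic limit $E[\xi_i] = \Theta/i$, and
$E[\text{total length}] = 2\sum_{i<n} 1/i$), and it reuses the same
simulator that generates the synthetic data.

Two numerical choices matter.

* **Common random numbers.** Replicate $r$ always uses the RNG stream
  keyed to $(\text{seed}, r)$, so the same seed produces the same
  genealogy stream at every parameter value.  The likelihood surface is
  then deterministic given the seed and smooth enough for Nelder–Mead.
* **Engine resolution $R$.** The default is $R = 10^4$ per evaluation
  (engine metadata records $R$, seed, and the regularization floor
  $\varepsilon = 10^{-12}\sum M$ applied to empty cells).  The residual
  Monte Carlo roughness of the surface scales as $1/\sqrt{R}$, and its
  effect on the *fit* grows with the number of SNPs, because the data
  term multiplies cell-level errors.  For spectra of a few thousand
  SNPs we found $R = 10^4$ sufficient for the size and time parameters
  but coarse enough to distort best-of-$k$ selection along the weakly
  identified $m$–$\nu$ ridge; the recovery and subsampling evaluations
  therefore use $R = 4\times 10^4$, at which the migration estimate
  stabilizes.  $R$ is configurable everywhere (`engineR`).

## The synthetic data generator

`simulateDataset()` draws, per locus, an independent genealogy, places
mutations as a Poisson process with intensity $\Theta_{loc}/2$ per unit
branch length (infinite sites, no intra-locus recombination), drops
loci with no mutation, and thins each retained locus to a single SNP
chosen uniformly among its mutations.  This mirrors a UCE-style
one-SNP-per-locus panel with complete phased calls.  Defaults:
$n_1 = n_2 = 6$ diploid individuals and $\Theta_{loc} = 0.05$ — the
per-locus scale implied by aggregate $\hat\Theta$ of order 100–200
spread over a few thousand loci in published UCE datasets.  Per-locus
RNG streams are keyed to the locus index, so extending the number of
attempted loci never reshuffles earlier loci; `simulateSNPPanel()`
exploits this to build panels with an exact number of variable loci
(datasets in this literature are reported by their variable-locus
counts).  The thinning policy (uniform choice among a locus's
mutations) is one of two defensible readings of one-SNP-per-locus
pipelines; picking the first SNP instead would not change any spectrum
expectation used here.

What the generator does *not* emulate: sequence-level structure
(quartets of bases, multiallelic sites), linkage between loci,
selection, missing data, phasing or polarization error, and more than
two demes.  Passing tests therefore demonstrate correctness of the
method under its own assumptions, not robustness to those real-data
complications.

## Spectra: folding, masking, subsampling

The fixed corners $(0,0)$ and $(2n_1, 2n_2)$ are always masked.  By
default spectra are folded onto minor-allele counts — the conservative
choice when no outgroup polarizes ancestral states; cells above the
half-frequency diagonal are masked, conjugate pairs are summed, and
diagonal pairs averaged so total mass is conserved.  A `polarized =
TRUE` switch preserves the unfolded path throughout.  Folding an
already-folded spectrum is an error, never a silent no-op.

`subsampleIndividuals()` draws $k$ diploid individuals per population
uniformly without replacement, keeps both haplotypes of each, and
removes loci rendered monomorphic by the draw (they carry no spectrum
information; the count is logged).  Between-population differentiation
is summarized by the Weir–Cockerham (1984) $F_{ST}$ as a ratio of
summed variance components, and lineages are classed as low
($F_{ST} < 0.05$) or high ($F_{ST} > 0.25$) divergence.

## Fitting protocol

`fitOnce()` maximizes the profiled composite likelihood by Nelder–Mead
in $\log_{10}$ parameter space with box bounds
$\nu \in [10^{-2}, 30]$, $T \in [10^{-3}, 10]$, $m \in [10^{-5}, 10]$
enforced by clipping; these are wide enough that empirically plausible
estimates are interior, and any estimate ending within 1% (log scale)
of a bound is flagged (`hitBounds`) because bound-pushing is a known
failure mode of subsampled fits.  Starts are nudged strictly inside
the box (2% of the log-range) so the initial simplex has room to move
in every coordinate.  `fitBestOf()` repeats the optimization $k$ times
(study protocol: 5) from starts jittered multiplicatively by
$2^{U(-1,1)}$ and keeps the run with the highest log composite
likelihood.  The "predetermined best-fit parameters" of the protocol
are interpreted as: the full-dataset optimum seeds every subsample
run, jittered per run.

## The subsampling experiment and SRMSE

`runExperiment()` mirrors the published protocol: for each symmetric
size $k$ from 1 to full$-1$, build 25 independent subsampled datasets
(independent across sizes, not nested), fit each best-of-5 starting
from the full-dataset optimum, and report per-size means ± SEM.  Failed
replicates (no variable loci left) are excluded, never resampled, and
counted.  Accuracy is summarized by

$$\mathrm{SRMSE} = \frac{\sqrt{\sum_i (\hat\theta_i - \theta)^2 / n}}
  {\bar{\hat\theta}},$$

with $\theta$ the full-data estimate, $\hat\theta_i$ the $n$ subsample
estimates, and the denominator the mean estimate *at that size* (not
the full-data value), which makes the measure scale-free and
comparable across lineages.  `regressSrmse()` then fits SRMSE on $N$
(diploid individuals per population) by OLS, pooling all non-blank
(lineage, $N$) cells.

## The packaged benchmark and its reproduction

`srmseBenchmark()` loads a checksummed fixture of published SRMSE
values for eight bird lineage pairs (five parameters × sample sizes
from full$-1$ down to 1), with lineage metadata ($F_{ST}$,
variable-locus counts).  `reproduceTable4()` recomputes the published
regression summaries from it:

```{r table4}
reproduceTable4()
```

Pooling all 49 (lineage, $N$) cells reproduces the published slope,
intercept and $r^2$ for $\nu_1$, $\nu_2$, $T$ and $\Theta$ to the
printed precision.  The $m$ regression is computed on the
low-divergence group only (as published) and flagged rather than
asserted: its published slope ($-0.00858$) is inconsistent with the
published table — the recomputed slope is $-0.08574$ while the
recomputed intercept (0.87715), $r^2$ (0.413) and $p$ (0.0007) match
the published row exactly, which points to a misprinted slope.  Which
four lineages form the low-divergence group is inferred from the
$F_{ST} < 0.05$ rule (it is not listed per lineage in the source); the
exact match of the other three statistics confirms the inference.

## Design choices on open points

* **Dataset size semantics.** Published one-SNP-per-locus datasets are
  reported by variable-locus counts, while the generator's `L` counts
  attempted loci (its mutation model must be allowed to produce
  invariant loci).  Evaluations that emulate published dataset scales
  therefore use `simulateSNPPanel()` to fix the number of variable
  loci; at the recovery truth used below, spectra of ~3,000 SNPs put
  estimator spread for $m$ near 16% (median), against ~30% at ~900
  SNPs — migration is by far the most weakly identified parameter, as
  the benchmark's own $m$ aberrancies at $N = 2$ also show.
* **Folded by default, polarized available.** The source protocol does
  not state its polarization; folded is the conservative default and
  the unfolded path is kept first-class.
* **Thinning choice** (uniform SNP per locus) documented above.
* **Independent subsampling across sizes** avoids correlations a
  nested design would induce.
* **Evaluation problem sizes.** The test-suite evaluations use 10
  replicate datasets (recovery) and a sizes-1:5 × 10-replicate ×
  best-of-3 experiment on one synthetic lineage; these are scaled-down
  profiles of the full 25 × 5 protocol, which remains available
  through the same functions.

## A worked example

```{r example, eval = FALSE}
truth <- splitMigParams(2, 4, 0.5, 0.5)
panel <- simulateSNPPanel(simConfig(6, 6, 12000, truth, 0.05, seed = 1),
                          3000)
full <- fitDataset(panel, start = truth, kRuns = 3, engineR = 40000,
                   engineSeed = 78, seed = 9)
exper <- runExperiment(panel, full, sizes = 1:5, reps = 10, runs = 3,
                       seed = 2024, engineR = 5000)
tab <- srmseTable(exper)
regressSrmse(tab, "nu1")
```

On synthetic lineages every parameter's SRMSE~$N$ slope is negative
(accuracy decays as individuals are removed).  The direction of the
*bias* at very small samples is parameter- and truth-dependent: at the
truth above, $\nu_1$ is under-estimated at $k \le 2$ (the under-
estimation of effective sizes reported for empirical lineages), while
$\nu_2$ is pushed *up* at 1:1 by the weakly identified migration–size
ridge.  The empirical under-estimation finding is a tendency of
large-$\nu$ lineages, not a guarantee of the composite-likelihood
estimator at every point of parameter space — the package's acceptance
test records this honestly: the $\nu_2$ direction check fails under
these study conditions while every SRMSE slope and the $\nu_1$
direction pass.

## Known limitations

The composite likelihood ignores linkage (none is simulated, but real
loci may violate this); one-SNP thinning slightly down-weights loci
with long genealogies relative to the Poisson field assumed by the
likelihood (negligible at $\Theta_{loc} = 0.05$); the Monte Carlo
engine's cost grows linearly in $R$ and quadratically-ish in sample
size, and its accuracy floor — not the data — can limit $m$ if $R$ is
set too low; no confidence intervals or model comparison are provided.
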