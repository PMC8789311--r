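---
title: "Inferring selective sweeps from local genealogies with sweepnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selective sweeps from local genealogies with sweepnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepnet)
```

## The problem and the model

A selective sweep — the rapid rise of a beneficial allele — leaves a
characteristic imprint on the genealogy of a sample of haplotypes at and
around the selected site: an excess of recent coalescence among the carriers
of the derived allele, and distorted genealogies at linked loci. The
ancestral recombination graph (ARG) of a sample is equivalent to an ordered
sequence of *local genealogies* along the genome, so the information
relevant to selection inference is carried by the shapes and node times of
the local tree at a focal site and its neighbours.

sweepnet turns this insight into a supervised-learning method:

1. **Encoding.** Each local genealogy is encoded as *lineage counts through
   time*: the number of ancestral branches crossing each of K discretized
   time points (default K = 100, generations before present, approximately
   log-uniform so recent times are resolved most finely). At the focal site
   the active lineages are split into those on the derived background (the
   mutation branch and its descendants) versus the ancestral background; for
   flanking genealogies only total counts are kept, capturing linkage
   disequilibrium. With two flanking trees per side this yields a 6-channel
   K-point feature — a 600-dimensional vector under the defaults.
2. **Training data.** Labeled regions are simulated with the package's own
   backend: a conditioned Wright–Fisher allele-frequency trajectory followed
   by a structured coalescent with recombination (details below).
3. **Model.** A two-stacked LSTM (100 units per stack, tanh activations)
   consumes the encoding one time point at a time, from the present into the
   past. Heads: a softmax pair trained with cross-entropy for sweep/neutral
   classification; a linear unit after the last time step trained with mean
   squared error for selection-coefficient (or onset-time) regression; and a
   linear unit at *every* time step (many-to-many) for allele-frequency
   trajectory inference. Optimization is Adam at its standard settings.
4. **Uncertainty.** Monte Carlo dropout: the dropout masks used as
   regularizers during training are kept active at inference, each stochastic
   forward pass samples a "thinned" network, and percentile intervals are
   read off the resulting predictive distribution.

## Conventions that make the encoding well-defined

Several small conventions are fixed once and used everywhere; tests enforce
them.

* **Branch activity** is half-open: a branch is active at time `t` iff
  `child_time <= t < parent_time`, so each coalescence reduces the count
  exactly once and the count at a node's own time is already reduced.
* **Root clamp.** For `t` at or above the root, the count is 1 (the
  persisting ancestral lineage), not 0. This avoids uninformative all-zero
  tails and keeps normalization meaningful.
* **Time grid.** `buildTimeGrid(K, tMax, curvature)` places
  `t_j = (exp((j/(K-1)) log(1 + c tMax)) - 1)/c`. Defaults `K = 100`,
  `tMax = 1e5` generations, `c = 1`; spacing is provably non-decreasing in
  `j`. Any approximately log-uniform grid works; this one is reproducible
  and two-parameter.
* **Channel order** is left-outermost … left-1, focal-ancestral,
  focal-derived, right-1 … right-outermost; row 1 is the present. The
  many-to-many trajectory head relies on this fixed time correspondence.
* **Flanking trees** are the nearest *distinct* genealogies by genomic
  interval (adjacent identical marginal trees are merged). At contig edges
  the outermost available tree is repeated, so the feature shape never
  changes.
* **Normalization.** Counts are divided by the sample size n by default
  (raw counts behind a flag), so models transfer across data sets with the
  same n and inputs stay in (0, 1].
* **Mutation-to-branch mapping** assumes biallelic sites without recurrent
  mutation: the unique branch whose subtended leaves equal the carrier set.
  For inferred (error-prone) trees an optional maximal-Jaccard best-match
  assignment exists behind an explicit flag, off by default.

## The simulation backend

The synthetic-data generator is first-class, tested code; its defaults *are*
the study conditions.

**Trajectory.** `simulateTrajectory()` runs a per-generation backward
Wright–Fisher process from the present-day frequency `f`: one deterministic
backward selection step (inverting `x' = x(1+s)/(1+sx)`, genic selection)
followed by binomial resampling among `2N(t)` copies, conditioned by
rejection (cap 1000 tries) on a single-copy origin. Soft sweeps run the
selection step only until the trajectory first drops below `f_init`
(latched), neutral before. The sampler was checked against an independent
*forward* Wright–Fisher oracle: at `s = 0.05`, `N = 10,000` the mean
0.05→0.95 traversal matches the deterministic logistic duration
`2 log(19)/log(1+s)` to about 0.3%; tests allow `max(3 SE, 1%)` to cover the
small discretization offset of the time reversal. Neutral increments are
tested as a martingale (conditioning on non-fixation makes the pooled mean
slightly negative, of order `f / path length`; the test tolerance accounts
for this).

**Genealogies and haplotypes.** `simulateRegion()` implements a structured
coalescent with recombination over `[0, L)` with Hudson-style tracking of
ancestral material. During the sweep phase lineages carry a background class
(derived/ancestral) with pairwise coalescence probabilities
`1/(2N x(t))` and `1/(2N (1-x(t)))` per generation; recombination moves the
fragment not containing the focal site to a random background; at the
allele's origin all derived lineages merge into the founding copy. Neutral
phases use exact geometric waiting-time skipping within constant-size
epochs. Coalescence edges are resolved into the tiling sequence of local
trees (unary nodes contracted, adjacent identical trees merged), and
mutations are dropped on each tree under the infinite-sites model
(positions uniform, branches weighted by length). The sweep's focal site is
placed at `L/2` with the derived-class leaves as carriers, so the sample DAF
is one binomial draw from the truth `f`.

Calibration facts enforced by tests: mean focal-tree TMRCA within Monte
Carlo error of `4N(1 - 1/n)`; mean per-bp diversity within 5% of
`theta = 4 N mu`; the neutral site-frequency spectrum proportional to `1/i`
(chi-square at alpha = 0.01); central-window Tajima's D depressed under
sweeps relative to neutral regions.

**Demographies.** Piecewise histories with optional within-epoch exponential
growth. Built-ins: constant-N; a CEU-like European history following the
standard Tennessen et al. (2012) parameterization (generation time 25
years), since that published model specifies the epoch table the package
needs; and a capuchino-seedeater-like history (derived Ne 130,000; ancestral
14,380,000 from 44,000 generations; root 1,450,000 beyond 1,850,000
generations) modeled as a single-population piecewise size history — the
divergence-time parameters are mapped onto size changes at the divergence
times, the simplest single-population reading of that configuration. All
built-ins are plain epoch tables and fully configurable.

**Priors.** CEU-like defaults: `s ~ U(1e-4, 0.02)`, `f ~ U(0.01, 0.99)`,
`mu, rho ~ U(1.25e-8, 2.5e-8)` per bp per generation; capuchino-like:
`s ~ U(0.001, 0.02)`, `f ~ U(0.25, 0.99)`, `f_init ~ U(0.01, 0.05)`,
`mu = rho = 1e-9`, soft mode. Sample sizes 198 (CEU-like), 56
(capuchino-like), 32 (reduced benchmark). Region length 100 kb with the
focal site at `L/2`. Neutral training regions get a DAF-matched focal site:
a target frequency drawn from the sweep `f` prior and a random segregating
site within 0.02 of it, so classes are not separable on frequency alone.

**Seeds.** A master seed fans out per-record child seeds recorded in the
dataset metadata; identical configuration and seed reproduce label arrays
bit-identically.

## Network choices the architecture leaves open

The architecture fixes stacks, units, activations, optimizer, losses and
heads; the remaining knobs are package choices, exposed in `netConfig()`:
dropout rate 0.2 applied after each stack (upward connections only; the
recurrent path stays undropped — the standard placement that keeps the
state dynamics stable), batch size 64, up to 40 epochs with early stopping
at patience 5 on a 10% validation split, Adam step size 1e-3, Glorot
initialization with forget-gate bias 1. Regression targets are standardized
internally (the natural-scale transform is stored in the checkpoint and
undone at prediction; s-estimates are clipped at 0, trajectory outputs to
[0, 1]). Intervals default to 95% percentile construction from 100 dropout
samples. All randomness flows through R's RNG, so training is exactly
reproducible under a seed on this single-threaded backend.

## Baseline statistics

For benchmarking, the package implements the classical windowed
summary-statistic feature set (ss, pi, Watterson's theta, Fay and Wu's
theta_H, Tajima's D, number of distinct haplotypes, Garud's H1/H12/H2-H1,
ZnS, max-omega) over five equal windows with per-statistic row-sum
normalization; region-level iHS (unstandardized log-ratio of EHH integrals
at every site with MAF > 5%, standardized in 50 derived-AF bins, averaged);
Manhattan-distance haplotype sorting; and the fixed-size genotype-image
encoder (focal variant centered, up to `halfWidth` variants per side, zero
padding). Choices the classical definitions leave open, fixed here: EHH
integration is trapezoidal over bp and truncated where EHH < 0.05
(configurable); iHS standardization bins with fewer than two scored sites
fall back to the global standardization; omega evaluates all splits with at
least one site per side (an empty within-side LD sum contributes zero, and
a vanishing cross-block sum yields an infinite omega, reported as such);
haplotype-sort ties break by original row index. Every statistic is tested
against an independent naive-enumeration oracle.

## Desk-scale experiment sizes

The test suite and the acceptance script run a scaled-down version of the
full study: constant `N = 10,000`, `n = 32` haplotypes, `L = 50` kb regions,
true genealogies, `s ~ U(0, 0.02)`. The suite uses 3,000 training and 500
held-out sweep regions plus 2,100 neutral regions and LSTM stacks of 32
units (24 for the classifier and trajectory model); the acceptance script
uses 2,000/1,200 regions. These sizes are the package's choice of a
desk-scale experiment: they are the point where the headline properties
(rank correlation of true and inferred s, near-zero estimates on neutral
regions, high AUROC for strong sweeps, power increasing with s) are stable,
while a full-scale run (10^6 regions of 100 kb, 198 haplotypes) is a
cluster-scale exercise that the package supports through the same
functions. Passing these tests shows the pipeline is correctly wired and
calibrated under its own generative model; it does not by itself establish
accuracy on real data, where ARG inference error, non-equilibrium
demography and recurrent mutation enter.

## Known limitations

* The simulator covers single-population piecewise demographies and a single
  selected site; no migration, no background selection, no recurrent
  mutation, no multiallelic sites.
* Features from *inferred* ARGs inherit the ARG tool's biases; the
  carrier-set/tree incompatibilities that real inferred trees produce are
  handled by the optional best-match mapping, which is deliberately off by
  default.
* The trajectory head predicts the frequency on the fixed grid; pre-origin
  time points carry label 0, so a predicted trajectory tail near 0 is
  indistinguishable from "allele did not exist yet" — by construction.
* Monte Carlo dropout intervals quantify model (weight-subnetwork)
  uncertainty, not simulation-misspecification error; the
  `robustnessGrid()` harness exists to probe the latter.

## A worked example

```{r example, eval = FALSE}
library(sweepnet)
set.seed(1)
dem <- demographyConstant(10000)
grid <- buildTimeGrid()

# one hard-sweep region and its feature
p <- sweepParams("hard", s = 0.01, f = 0.8, mu = 1.5e-8, rho = 1.25e-8)
reg <- simulateRegion(p, dem, L = 5e4, n = 32)
fv <- regionFeatures(reg, grid)

# a small labeled dataset and a regressor
ds <- makeDataset(nNeutral = 200, nSweep = 600, demography = dem,
                  prior = priorSpec(sRange = c(0, 0.02)),
                  L = 5e4, n = 32, grid = grid, seed = 1)
fit <- trainModel(ds, config = netConfig("regress_s", unitsPerStack = 32,
                                         maxEpochs = 20, seed = 1))
predictWithDropout(fit, fv, nSamples = 100)
```
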