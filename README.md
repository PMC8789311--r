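# sweepnet

Detecting selective sweeps and inferring selection coefficients and
allele-frequency trajectories from the local genealogies of an ancestral
recombination graph (ARG), for population geneticists who have (or can
simulate) timed genealogies of a haplotype sample.

## The method

A sweep leaves a burst of recent coalescence among the carriers of the
beneficial allele and distorts linked genealogies. sweepnet encodes a focal
site's genealogy as **lineage counts through time**: on a fixed grid of
K = 100 discretized time points t_0 = 0 < … < t_99 (generations before
present, approximately log-uniform, finest near the present), it records the
number of active *ancestral* and *derived* lineages of the focal tree —
where the derived lineages are the mutation branch and its descendants, the
branch being the unique one whose subtended leaves equal the derived-allele
carrier set — plus the total lineage counts of the two nearest distinct
genealogies on each side, which carry the linkage-disequilibrium signal.
Counts are normalized by the sample size n. The result is a fixed
600-dimensional feature (K × 6 channels).

These features feed a two-stacked LSTM (100 tanh units per stack, Adam,
softmax/cross-entropy for sweep-vs-neutral classification, linear/MSE for
selection-coefficient s and onset regression, and a many-to-many linear head
for per-timepoint allele-frequency trajectories). Training data come from
the package's own simulator: a per-generation Wright–Fisher allele-frequency
trajectory conditioned on a single-copy origin, then a structured coalescent
with recombination in which derived/ancestral lineage classes coalesce at
rates 1/(2N x(t)) and 1/(2N(1−x(t))) set by the trajectory. Uncertainty
comes from Monte Carlo dropout: stochastic forward passes with the dropout
masks active yield a predictive distribution and percentile intervals.

Baselines from the classical toolbox are included and oracle-tested:
windowed summary statistics (π, θ_W, θ_H, Tajima's D, H1/H12/H2-H1, ZnS,
max-ω, …), region-level iHS, Manhattan-distance haplotype sorting and the
fixed-size genotype-image encoder, plus ROC/AUROC, regression-error and
stratified evaluation harnesses.

## A worked example

```r
library(sweepnet)
set.seed(1)
dem  <- demographyConstant(10000)        # constant N = 10,000 diploids
grid <- buildTimeGrid()                  # 100 points, 0..1e5 generations

p   <- sweepParams("hard", s = 0.01, f = 0.8, mu = 1.5e-8, rho = 1.25e-8)
reg <- simulateRegion(p, dem, L = 5e4, n = 32)
reg
#> SimulatedRegion: 32 haplotypes, 112 sites, 57 local trees over [0, 50000) (hard, constant-N10000)
reg@focalSite
#> SiteLabel: position 25000, 23/32 derived carriers (DAF 0.719)

fv <- regionFeatures(reg, grid)
fv
#> FeatureVector: 100 timepoints x 6 channels (normalized, n = 32)
#>  channels: left2_total, left1_total, focal_anc, focal_der, right1_total, right2_total
round(featureValues(fv)[1:3, ], 3)
#>      left2_total left1_total focal_anc focal_der right1_total right2_total
#> [1,]           1           1     0.281     0.719            1            1
#> [2,]           1           1     0.281     0.719            1            1
#> [3,]           1           1     0.281     0.719            1            1
```

Row 1 is the present: every haplotype is its own lineage (totals 1 after
normalization), and the focal channels split 9/32 ancestral vs 23/32 derived
— the derived channel at time 0 *is* the derived allele frequency. Deeper
rows decay towards 1/n as lineages coalesce; under a sweep the derived
channel collapses much faster than neutrality predicts, which is the signal
the LSTM learns.

Training and prediction:

```r
ds  <- makeDataset(nNeutral = 200, nSweep = 600, demography = dem,
                   prior = priorSpec(sRange = c(0, 0.02)),
                   L = 5e4, n = 32, grid = grid, seed = 1)
fit <- trainModel(ds, config = netConfig("regress_s", unitsPerStack = 32,
                                         maxEpochs = 20, seed = 1))
predictWithDropout(fit, fv, nSamples = 100)   # point estimate + 95% interval
```

A thin CLI over the same functions ships at `inst/cli/sweepnet.R`
(subcommands `simulate`, `extract`, `train`, `predict`, `evaluate`,
`fixtures`); external genealogies enter as Newick + a BED-like interval
sidecar via `readLocalTrees()`, and derived-allele carriers from a phased
VCF with an AA (ancestral allele) INFO field via `readCarriersVcf()`.

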