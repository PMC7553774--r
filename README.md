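# nevusdyn

Stochastic and analytic models for a precise question in melanocyte
biology: **why do benign nevi ("moles") stop growing?** A BRAF-activated
melanocyte clone proliferates and then arrests within weeks. The standard
explanation — oncogene-induced senescence, a cell-autonomous switch — makes
quantitative predictions about clone-size distributions and arrest timing
that can be checked. This package implements both model families and the
statistics needed to compare them with data:

* **Cell-autonomous arrest** (`simulateClones`, `cloneSizePmf`,
  `extinctionByGeneration`, `minArrestProb`, `medianSizeSweep`,
  `minStagesForMedian`): Galton-Watson branching in which each daughter
  cell advances through `k` stages with probability `s` per cycle,
  arresting on leaving the last. The exact clone-size law is
  `P(N = n) = C(n-1) s^n (1-s)^(n-1)` (Catalan numbers `C`), whose
  near-critical `n^{-3/2}` power-law tail is scale-free — heavy-tailed in
  a way real nevus sizes are not.
* **Renewal control** (`simulateFeedbackEnsemble`, `solveFeedbackODE`,
  `meanFieldTrajectory`): offspring remain dividing with probability
  `p(A) = p_max K / (K + A)` falling with the arrested count `A`
  (half-max `K` = 50 arrested cells) — an integral negative feedback that
  stops clones semi-synchronously and yields narrow, approximately
  log-normal sizes.
* **A spatial Cellular Potts model** (`runSpatialSimulation`): cells as
  pixel domains on a 300x300 lattice; arrested cells secrete a diffusing,
  decaying signal (decay length 15 px) that raises the arrest probability
  of dividing neighbours at division; ~382 Monte Carlo steps per cell
  cycle. Core dynamics in C++.
* **Gene-signature scoring** (`clusterProfiles`, `normalizeLog2`,
  `summedScore`, `nSemOrder`): per-cluster summed log2 scores of
  senescence/proliferation signatures on a clustered single-cell matrix.
* **Nest neighbourhood statistics** (`neighborSizeHistograms`,
  `permutationEnvelope`, `medianNestSpacing`): mean neighbour sizes in
  45 µm annuli around nests modelled as equivalent-area disks, against a
  within-field area-permutation null with 5th/95th percentile envelopes.
* **Synthetic data with ground truth** (`generateNestFields`,
  `generateExpression`, `generateCloneFixture`) and plain-text IO
  (`readNestTable`, `readExpressionMatrix`, `readSignatures`).

## A worked example

How strict must a one-hit arrest switch be, and what does it do to clone
sizes?

```r
library(nevusdyn)

## smallest per-cycle arrest probability giving 99% clonal arrest
## within 30 cell cycles (bisection, 20,000 clones per evaluation)
s99 <- minArrestProb(stages = 1, target_fraction = 0.99, n_sims = 20000,
                     seed = 42)
round(as.numeric(s99), 3)
#> [1] 0.556

## ...but at s barely above that regime, clones stay tiny:
m <- meanSizeAtHorizon(StageModelParams(s = 0.53), n_sims = 20000, seed = 42)
round(as.numeric(m), 1)
#> [1] 15.3

## and the size law is a scale-free 3/2 power law:
round(tailExponent(function(n) cloneSizePmf(n, s = 0.5), c(100, 1000)), 3)
#> [1] 1.501
```

So a single-stage switch strict enough to arrest clones on time caps the
mean clone at ~15–19 cells — far below the hundreds of cells in a real
nevus — and predicts heavy-tailed sizes. Collective feedback does better:

```r
ens <- simulateFeedbackEnsemble(FeedbackParams(), 9115, seed = 42)
round(mean(ens$final_arrested), 1)                      # mean final size
#> [1] 231.5
round(sd(ens$final_arrested) / mean(ens$final_arrested), 2)   # CV
#> [1] 0.27
br <- simulateClones(StageModelParams(s = 0.56), 20000, seed = 42)
round(sd(br$size) / mean(br$size), 2)   # branching CV at the same horizon
#> [1] 1.69
```

Feedback clones reach hundreds of cells with a CV of 0.27 (log sizes fit
mu = 5.36, sigma = 0.61); the matched branching ensemble is six times more
dispersed. On the spatial side, the permutation machinery detects planted
short-range inhibition in synthetic nest fields:

```r
nf <- generateNestFields(n_fields = 7, inhibition_amplitude = 0.5,
                         inhibition_range_um = 45, seed = 42)
env <- permutationEnvelope(nf, n_perm = 1000, seed = 42)
round(env$size_proximity$correlation, 2)   # radius vs crowding load
#> [1] -0.48
env$size_proximity$p_value
#> [1] 0.000999001
```

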