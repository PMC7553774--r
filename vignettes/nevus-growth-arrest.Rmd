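---
title: "Models of nevus growth arrest: cell-autonomous versus collective"
author: "nevusdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of nevus growth arrest: cell-autonomous versus collective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nevusdyn)
```

# The scientific question

Benign melanocytic nevi ("moles") arise when an activating BRAF mutation
drives a melanocyte clone to proliferate — and then, within two to three
weeks in the mouse, the clone stops growing. The conventional explanation is
oncogene-induced senescence (OIS): a cell-autonomous stress response that
switches each cell off independently. `nevusdyn` implements the quantitative
machinery needed to ask whether that explanation is compatible with what
nevi actually look like: their size distributions, the timing of their
arrest, their gene expression, and the spatial arrangement of the
melanocyte nests inside them.

The package's models fall into two families:

* **Cell-autonomous**: each cell arrests independently with some
  probability per cell cycle, possibly after passing through several
  sequential stages. These are Galton-Watson branching processes.
* **Collective**: cells that have arrested tell their neighbours to arrest
  too — renewal control, an integral negative feedback that normal tissues
  use to regulate size — implemented both as a well-mixed stochastic model
  and as a spatial Cellular Potts model with a diffusible arrest signal.

Helper modules provide the gene-signature score used to ask whether nevus
melanocytes look senescent, the annulus/permutation statistics used to ask
whether neighbouring nests inhibit each other, synthetic-data generators
with known ground truth, and plain-text readers/writers for every format
involved.

# The cell-autonomous (stage) model

A clone starts from one founder. Cycles are synchronous. In the default
`founder_divides` variant, every proliferating cell divides each cycle and
each daughter then independently advances one "stage" with probability
$s$; advancing out of the last of $k$ stages is permanent arrest. With
$k = 1$ this is the textbook one-hit model: each daughter arrests with
probability $s$ per cycle. The `founder_may_arrest` variant applies the
test *before* division (so a clone can end as a single arrested cell);
it admits the cleanest closed form and is retained as an option. The
update order is genuinely ambiguous in verbal descriptions of such models;
`founder_divides` was chosen as the default because its thresholds and
mean sizes line up best with the headline numbers (see the acceptance
script), and both variants are exposed everywhere.

Three analytic companions keep the Monte Carlo honest:

* `cloneSizePmf()` — the exact total-progeny law. For `founder_may_arrest`,
  $P(N = n) = C_{n-1} s^n (1-s)^{n-1}$ with $C_m$ the Catalan numbers
  (the clone is a random binary tree whose leaves are arrested cells);
  the forced-division variant is the convolution of two such trees,
  $C_{n-1} s^n (1-s)^{n-2}$. Catalan numbers are evaluated through
  `lgamma` so the law is usable to $n = 10^6$ and beyond. For $s$ near
  $1/2$ the law decays as $n^{-3/2}$: a scale-free power law, which is why
  truncating simulated distributions at any observability threshold leaves
  their shape unchanged — and why such models cannot produce the log-normal
  size distributions real nevi show.
* `extinctionByGeneration()` — the generating-function recursion for the
  probability that all proliferation has ceased by generation $g$
  ($q_g = s + (1-s) q_{g-1}^2$ in the simplest case, a per-stage system
  otherwise). It is the oracle for arrest-time quantiles.
* the closed-form eventual mean, $s/(2s-1)$ per subtree (twice that with
  the forced first division), used in moment checks.

The population-level simulator `simulateClones()` tracks per-clone stage
counts with binomial draws, which is exact because cells within a clone are
exchangeable; 20,000 clones over 30 cycles take well under a second.
`minArrestProb()` bisects $s$ against a fresh ensemble per evaluation
(tolerance $\pm 0.005$, 20,000 clones each), `medianSizeSweep()` maps
(stages, probability, truncation threshold) to truncated medians and arrest
fractions, and `minStagesForMedian()` extracts the smallest stage count
that can deliver a given median under two constraints: at least 95% (or
99%) of clones must arrest within 30 cycles, and the truncated median must
be at least twice the truncation threshold (otherwise the "observed"
median would be an artifact of the observability cutoff). The default
probability grid steps by 0.02 over $[0.5, 0.98]$ and the threshold grid
doubles from 0 to 1600 cells, spanning the plausible observability range.

```{r branching, eval = FALSE}
s99 <- minArrestProb(stages = 1, target_fraction = 0.99, seed = 1)
meanSizeAtHorizon(StageModelParams(s = 0.53), n_sims = 20000, seed = 1)
tailExponent(function(n) cloneSizePmf(n, s = 0.5), c(100, 1000))
```

# Renewal control (collective arrest)

In the feedback model, every division produces two offspring and each
offspring *remains dividing* with probability
$p(A) = p_{\max} K^h / (K^h + A^h)$, where $A$ is the number of cells that
have already arrested, $K = 50$ arrested cells is the half-max and $h = 1$
the Hill coefficient. The arrested pool only grows, so it integrates the
clone's history: an integral negative feedback. Defaults place the final
size in the low hundreds of cells, stopping in 13–14 cycles with a
stopping-time CV under 20% — the clock-like behaviour that yields narrow,
approximately log-normal size distributions.

Two deliberate choices deserve note:

* **`p_max = 0.9`, not 1.** At $p_{\max} = 1$ exactly, the arrest flux
  $1 - p(0)$ is zero before any cell has arrested, so a clone started from
  a single cell can never seed the feedback and grows without bound, in
  both the stochastic and deterministic forms. Any $p_{\max} < 1$ removes
  the degeneracy; 0.9 keeps early growth strongly supercritical while
  seeding arrest at a realistic rate. It is configurable.
* **Two deterministic companions.** `solveFeedbackODE()` integrates the
  continuous-time form $dP/dt = (2p-1)\,rP$, $dA/dt = 2(1-p)\,rP$ with
  $r = \ln 2 / \text{cycle time}$ (deSolve, `lsodar`, root-stopped at
  $P < 0.5$); it is exactly invariant to cycle-time rescaling and carries
  the robustness analysis. `meanFieldTrajectory()` iterates the discrete
  cycle map $A \leftarrow A + 2(1-p)P$, $P \leftarrow 2pP$, which is the
  true large-$K$ limit of the synchronous stochastic scheme (the two
  deterministic forms differ in their overshoot past the critical point
  $p(A^*) = 1/2$, because a per-cycle growth factor of $2p$ is not
  $2^{2p-1}$). The ensemble mean agrees with the cycle map to ~3% at
  defaults and under 1% at $K = 500$; the ODE is kept for the
  continuous-time questions it answers exactly.

On log-normality: ensembles of final sizes are *well fit* by a log-normal
(the fitted $(\mu, \sigma)$ from `logNormalFit()` describe the bulk
closely), but a formal normality test on log sizes at ensemble sizes in
the thousands rejects, for a structural reason: starting from one cell,
both daughters arrest at the first division with probability
$(1-p_{\max})^2$, leaving an atom of two-cell clones (~1% of runs at
defaults) that no log-normal accommodates, and the bulk retains a mild
negative skew. The package reports the Lilliefors test honestly rather
than hiding the discrepancy; the scientifically meaningful contrast — a
size CV several-fold smaller than any branching model matched to the same
mean, and stopping times that concentrate — is what the tests assert.

# The spatial (Cellular Potts) model

`runSpatialSimulation()` implements a minimal CPM: cells are pixel domains
on a square lattice (default $300 \times 300$), evolving by Metropolis
pixel-copy attempts under contact energies plus a quadratic volume
constraint ($\Delta H$ accepted with probability
$\min(1, e^{-\Delta H/T})$; one MCS = lattice-size$^2$ attempts;
8-neighbour contacts, $J(\text{cell},\text{medium}) = 16$,
$J(\text{cell},\text{cell}) = 8$, $\lambda = 2$, $T = 10$). A founder of
25 px² grows by inflating its target area at one of three rates (redrawn
each division) and divides along a uniformly random plane through its
centroid when its *realized* pixel area reaches a division area drawn in
$[72, 80]$ px². Triggering on realized rather than target area makes
division self-limiting under crowding (a cell squeezed below its target by
neighbours waits); an isolated cell equilibrates a few pixels below target
(interface tension vs the volume constraint), which the growth rates
absorb: the realized mean inter-division interval at defaults is ~382 MCS.

At each division, each daughter arrests with probability
$\min(1,\ 0.01 + 0.95\, c^2/(c^2 + 5^2))$ where $c$ is the secreted-signal
concentration at its centroid pixel — a 1% baseline floor plus a Hill
augmentation. Arrested cells secrete at 1 unit per pixel per MCS; the
field obeys $\partial c/\partial t = D \nabla^2 c - k c + \text{source}$
with $D = 1$, $k = 1/225$ (decay length $\sqrt{D/k} = 15$ px), zero-flux
boundaries, integrated with 6 explicit sub-steps per MCS (stability
requires $(4D + k)\,\Delta t \le 1$; the constructor refuses unstable
configurations). The Hill amplitude, half-max and secretion rate are not
published quantities; they were calibrated once so that the stated
observables hold — decay length 15 px, ~382 MCS per cycle, and full arrest
of every default run within roughly ten generations (a few hundred cells)
— and all are exposed in `PottsParams`. The solver is validated against
the screened-Poisson Green's function: the steady point-source profile
matches $K_0(r/15)$ within a few percent, and the decay length is
recovered by regressing $\log(c\sqrt{r})$ on $r$ (the $\sqrt{r}$ factor
removes the 2D geometric bias that a naive log-slope carries).

The per-attempt energy bookkeeping is tested against a full-Hamiltonian
recomputation, divisions conserve pixels and split near-evenly at uniform
angles, mass balance of the field solver is exact up to sources and decay,
and seed-identical runs are bit-identical (a single RNG stream drives
every stochastic element).

# Signature scoring

For a clusters-labelled expression matrix (a `SummarizedExperiment`,
genes × cells), `clusterProfiles()` computes per-cluster means and SEMs;
`normalizeLog2()` forms $\log_2$ ratios of cluster means to the average
over all cells of the comparison set (the whole experiment, or a subset
such as only the melanocyte clusters — per *cell*, not per cluster, so
large clusters weigh more, matching how an average transcriptome is
actually assembled). Zeros are handled with a pseudocount defaulting to
one tenth of the smallest positive cluster mean. `summedScore()` adds the
log ratios over a signature's genes in each cluster: random up/down
variation cancels, consistent trends accumulate. `nSemOrder()` ranks genes
by their normalized SEM in their least-noisy cluster, the reliability
ordering used to sort heatmaps. Genes missing from the matrix are dropped
and counted, mirroring how cross-species signatures lose unmapped
orthologs. Signature files load from GMT or plain lists; ortholog mapping
is upstream of this package.

The statistic's validity is established on synthetic data:
`generateExpression()` plants directional fold changes in chosen clusters
of a negative-binomial count matrix (dispersion 0.5, per-cell library-size
normalization), and the planted cluster is recovered as the top-scoring
one in ≥ 99 of 100 replicate matrices, while random same-size gene sets
stay inside the resampling null band.

# Nest neighbourhood statistics

Nests are modelled as disks of equivalent area
($r = \sqrt{\text{area}/\pi}$). For each target nest, the mean equivalent
radius of neighbours whose centers lie within (target radius + 45 µm) is
computed — the annulus extends from the target's perimeter, and the
*center* of a neighbour decides membership (the neighbour's own perimeter
is offered as the `rule = "edge"` option; the choice is a documented
convention, as is the fixed 5 µm histogram binning). Targets with no
neighbour in range are excluded rather than zero-imputed. Fields with
fewer than 10 nests are dropped. Histograms are split by target size at a
20 µm radius (ties going to "large" and logged), and a 150 µm annulus is a
one-argument re-run.

The null model permutes nest areas within each field, positions fixed
(5000 permutations by default, seeded), and the per-bin 5th/95th
percentiles of the permuted histograms form the envelope. Because the
binned statistic is integer-valued, a strict "outside the envelope" rule
is conservative under ties (measured ~2% where 10% is nominal); the
per-bin flags therefore use the exact Monte Carlo rank test with uniformly
randomized tie-breaking, which restores the nominal two-sided 10% level in
every bin by exchangeability — verified by a 200-replicate calibration in
the test suite. The plain strict comparison is also returned
(`flags_strict`). Two scalar summaries with permutation p-values
accompany the envelope: the difference between large- and small-target
class means, and the correlation of nest radius with an exponential
crowding load — the targeted alternative for short-range growth
inhibition, which detects the synthetic inhibition generator at
amplitude 0.5 / range 45 µm essentially always while holding its 5% level
under the null.

"Median nest spacing" is operationalized as the median nearest-neighbour
center distance (the quantity is not otherwise defined); on default
synthetic fields it lands near the ~79 µm the real P21 data show.

# Synthetic data: what it does and does not establish

`generateNestFields()` places nests by a homogeneous Poisson process
(default ~70 nests/mm² in 600 µm fields, i.e. ~25 nests per field, like
the real seven-field data) with log-normal radii (median ~19 µm, straddling
the 20 µm size split); optional inhibition multiplies each radius by
$1 - a \sum_j e^{-d_{ij}/\text{range}}$. `generateExpression()` and
`generateCloneFixture()` were described above. These generators give every
analysis stage inputs with known ground truth; passing tests demonstrate
that the machinery recovers planted structure and holds its nominal error
rates. They do not demonstrate anything about real nevi: the real nest
data have field-to-field heterogeneity and segmentation noise the Poisson
model lacks, and real single-cell matrices have richer covariance than
independent negative binomials. Conclusions about the biology require the
study's own tables, which are consumed through the same readers
(`readNestTable()`, `readExpressionMatrix()`, `readSignatures()`).

# Numerical and scale choices

Ensembles default to 20,000 clones per Monte Carlo evaluation (the
headline thresholds move by less than the bisection tolerance beyond
that); the stage-count sweeps use probability steps of 0.02 and a doubling
threshold grid, which resolve the 4-vs-5 and 6-vs-7 stage questions
without an exhaustive grid. Potts unit tests run on 150–250 px lattices —
the physics (decay length, cycle length, arrest wave) is
lattice-size-independent well above the clone diameter — while the default
parameter object keeps the full 300 px lattice. Every stochastic entry
point takes an explicit seed and derives per-clone or per-evaluation
sub-streams deterministically; equal seeds reproduce results bit for bit.

# Known limitations

* The two branching variants bracket, but cannot resolve, the update-order
  ambiguity of verbal one-hit models; headline quantities are reported for
  the default variant with tolerance bands covering both.
* The renewal-control model has no cell death, no reversible arrest, and a
  single well-mixed compartment; the Potts model omits chemotaxis,
  differential adhesion and 3D structure, and its Hill/secretion constants
  are calibrated rather than measured.
* The log-normality of feedback ensembles is a bulk description, not a
  test-passing property at large ensemble sizes (see above).
* The spatial statistics implement one fixed neighbour-inclusion rule and
  binning; conclusions that depend on those conventions should be checked
  under the provided alternatives.
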