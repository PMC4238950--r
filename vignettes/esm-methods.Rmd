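---
title: "An epidemic spreading model of misfolded-protein propagation on brain connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An epidemic spreading model of misfolded-protein propagation on brain connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmspread)
```

## The model

`esmspread` treats the brain as a system of N structurally interconnected
gray-matter regions. Each region i carries a probability $P_i(t)$ of
misfolded-protein (MP) burden — for amyloid-beta, the probability that the
region harbors established deposits at day $t$. Misfolded proteins behave
like infectious agents: deposits seed the production of new soluble
infectious-like factors, those factors travel along white-matter fibers to
connected regions, and an immune-like clearance response removes them. The
state equation is a stochastic SIS-type balance on a daily grid:

$$
P_i(t + \Delta t) = P_i(t) + \Delta t\,\big[(1 - P_i(t))\,R_i(t)
  - P_i(t)\,\delta_i(t)\big] + \mu\,\Delta t
  + \sigma \sqrt{\Delta t}\, Z_{i,t},
$$

clipped to $[0, 1]$ after every step. The three pieces:

**Reception.** The probability that region i receives infectious-like
factors accumulates endogenous and exogenous sources as a complement of
products,

$$
R_i(t) = 1 - \big(1 - \beta_i^{\mathrm{int}}(t)\big) \prod_{j \ne i}
  \big(1 - ACP_{ji}\, \beta_j^{\mathrm{ext}}(t - \tau_{ji})\big),
$$

where $ACP_{ji}$ is the anatomical connection probability between j and i
(self-connections fixed at 1 but excluded from the product; self-seeding is
the intrinsic term) and $\tau_{ji} = \mathrm{round}(d_{ji} / V_{MP})$ is
the transport delay over the fiber of length $d_{ji}$ mm at speed $V_{MP}$
mm/day. The delayed history before the outbreak ($t < 0$) is the clean,
zero-deposition state: the outbreak begins at $t = 0$, and a region's
first exogenous input arrives only after the corresponding fiber delay.

**Production and its split.** The total production rate of a region is a
normalized logistic in its own deposition,
$\beta^{\mathrm{tot}}(P) = \min(\beta_0, 1)\, L(P)$ with $L(0) = 0$,
$L(1) = 1$: established deposits seed new misfolding (nucleation), trace
levels produce almost nothing. The global deposition inequality, measured
by the Gini coefficient $g(t)$ of the current regional vector, splits this
total into an exported part $\beta^{\mathrm{ext}} = g\,\beta^{\mathrm{tot}}$
(soluble factors diffusing down concentration gradients toward other
regions) and a retained part
$\beta^{\mathrm{int}} = (1 - g)\,\beta^{\mathrm{tot}}$; the two always sum
back to the total.

**Clearance.** The clearance rate declines exponentially with local burden,
$\delta(P) = \min(\delta_0, 1)\, e^{-\rho P}$: deposition brings
inflammation and cell death, collapsing the capacity to remove new factors.

Each subject is characterized by four free parameters: the production
amplitude $\beta_0$, the clearance amplitude $\delta_0$, the residual noise
level $\sigma$, and the onset age implied by the matched simulation day.
The marginalized global rates $\beta_{\mathrm{eff}} = \int_0^1
\beta^{\mathrm{tot}}(p)\,dp$ and $\delta_{\mathrm{eff}} = \int_0^1
\delta(p)\,dp$ (1001-point trapezoidal quadrature) summarize the rate
functions independently of any particular trajectory.

## Shape constants and the dynamical regime

The shape constants are fixed package defaults, not fitted, and they were
chosen to place the model in the regime the biology describes: deposition
that, once established, persists for decades and spreads outward along
fibers over decades.

* `sigmoid_mid = 0.45`, `sigmoid_slope = 10` (production midpoint and
  steepness). Production switches on only once deposition is substantial.
  With an early midpoint, the background floor (below) self-ignites every
  region regardless of connectivity and the connectome becomes irrelevant;
  with the late midpoint, quiescent regions stay quiescent until infectious
  input actually arrives, so outbreaks propagate as fronts gated by the
  fiber delays.
* `clearance_decay = 4.5` (about a 90-fold collapse of clearance at full
  deposition). Together with the production sigmoid this makes the local
  dynamics bistable: a low clean state and a high deposited state separated
  by a barrier. Arrived fronts push regions over the barrier; deposits then
  persist, which is exactly the clearance-deficiency mechanism the model is
  built around. Smaller values let the deposited state decay back after the
  front passes; much larger values pin every equilibrium indistinguishably
  close to 1.
* `p_seed_init = 0.6`. The outbreak regions start as an established focus
  above the bistable barrier for the whole physiological amplitude range
  (production 0.3-0.9, clearance 0.1-0.5). Trace seeding (say 0.01) falls
  below the barrier whenever clearance is moderate, and the epidemic never
  starts.
* `noise_mean = 0.001` per day. A small constant background production that
  keeps every region at a low clearance-dependent floor
  ($\approx \mu / \delta_0$, i.e. 0.2-1% deposition probability). It is a
  realistic nonzero baseline (PET never measures exactly zero), and it
  anchors the absolute scale of the amplitudes: without it, jointly
  rescaling $(\beta_0, \delta_0) \to (c\beta_0, c\delta_0)$ approximately
  rescales time, which matching over the free day absorbs, leaving the two
  amplitudes identifiable only through their ratio. The floor level breaks
  that symmetry.
* `velocity = 0.01` mm/day. Anatomical fiber lengths of 20-150 mm then
  imply inter-region lags of 5-40 years, so whole-brain progression unfolds
  across the 50-year horizon (`horizon_days = 18250`), matching the
  decades-long staging of amyloid pathology. Bulk transport of misfolding
  activity between cortical regions is far slower than axonal transport of
  individual vesicles; this constant is the package's single most
  consequential timescale choice and is fully configurable.

Degenerate and boundary cases are handled explicitly: an all-zero state has
Gini 0 by convention; rates are clamped into $[0,1]$; the state is clipped
to $[0,1]$ after every Euler-Maruyama step (the noise term is omitted when
no RNG seed is supplied, giving the deterministic skeleton); transmission
delays round to the nearest whole step; ties in the optimal matching day
break toward the earliest day.

## PET calibration

Regional deposition probabilities are derived from voxel signals by
extreme-value calibration against a non-specific-binding reference region
(cerebellum in the amyloid application): bootstrap sub-samples of the
reference voxels (40,000 draws of 100 voxels by default) yield a
distribution of sub-sample maxima, fitted by a Gumbel distribution via
maximum likelihood (`fitdistrplus`). A voxel's deposition probability is
the fitted CDF at its signal — the probability of exceeding the reference
region's plausible maxima — and a region's probability is the mean over its
voxels (a max-based aggregation is available behind a flag). The Gumbel
family is the natural choice for maxima of light-tailed signals; the
sub-sample size is not identified by the procedure itself and defaults to
100. The within-region mean is the simplest reading of a regional
deposition probability; at 500 voxels per region it resolves regional
differences of about 0.015 in probability, which is why rank-recovery
checks use graded patterns rather than near-tied floors.

## Fitting: seed search and per-subject estimation

Subjects are fitted by trajectory matching: for candidate amplitudes the
deterministic skeleton is simulated from the outbreak set over the full
horizon, and the optimal day is the earliest day minimizing the Euclidean
distance between simulated and observed patterns. $\sigma$ is estimated
from the residuals at that day; the onset age is the chronological age
minus the matched day.

The objective's geometry drives the optimizer design. The amplitude-scaling
direction is a shallow valley (see above), with spurious local minima that
can out-score the true basin on a coarse grid. The search therefore runs: a
12x12 log-spaced grid on $[10^{-3}, 1]^2$; Nelder-Mead refinement in log
space from the best point of every block of a 3x3 partition of that grid
(so every candidate basin contributes a start); then two rounds of a sweep
of the scaling family through the incumbent plus full-range line searches
along each amplitude axis, each followed by re-refinement. On synthetic
cohorts this recovers the generating amplitudes essentially exactly
whenever the snapshot is informative.

Identifiability has a real boundary worth stating. A snapshot taken before
the first fiber arrival shows only the seed plateau and the background
floor — two level groups. With the matching day free, a one-parameter curve
of amplitude pairs reproduces such a pattern exactly, and only the
clearance amplitude (pinned by the floor) is recovered; the production
amplitude is genuinely unidentifiable from that observation. The
synthetic-data generator therefore places the outbreak set on the most
central regions (as the cingulate outbreak is anatomically central), which
shortens the uninformative pre-arrival window, but snapshots in the first
couple of simulated years can still under-determine $\beta_0$. This is a
property of the inverse problem, not of the optimizer.

Group-level seed identification scores a candidate outbreak set by the
cohort mean of the per-subject minimal distances; exhaustive enumeration is
budget-guarded by the exact combinatorial count (C(78, 6) = 256,851,595 for
the full atlas at set size 6 — supported in principle, not a desktop path),
with a greedy forward search as the fallback. Greedy search can commit to a
best singleton that is not part of the best pair when the cohort was
generated from a two-front outbreak; the exhaustive path is authoritative
whenever its budget allows.

## Network analyses

Effective anatomical distance from the outbreak set uses edge lengths
$1 - \ln(ACP)$ (a certain connection has length 1; rare connections are
long), the convention under which epidemic arrival times grow linearly with
distance from the outbreak; $1/p$ and $-\ln p$ are available alternatives.
Multi-source distance is the minimum over the outbreak set. Arrival times
are first threshold crossings (thresholds 0.1/0.5/0.9 in the analyses);
regressions of arrival time on distance exclude unreached regions pairwise.
Hub vulnerability is the Pearson correlation between weighted degree
(off-diagonal ACP row sums) and arrival time with the seeds excluded.

The connectome null model rewires the binarized topology by Maslov-Sneppen
double-edge swaps (igraph), preserving the binary degree sequence exactly
and the weight multiset exactly; weights are then re-assigned to edges by
rank-matching combined endpoint strengths, preserving node strengths
approximately (rank correlation above 0.9 on 50-region graphs). Fiber
lengths travel with their paired weight. The contrast statistic is the
cohort-mean explained variance ($100 r^2$) on the true versus rewired
connectomes, with the add-one empirical p-value
$(1 + \#\{null \ge true\}) / (n_{\mathrm{random}} + 1)$, never exactly
zero. Split-half cross-validation aggregates training-half fits by the
median (robust to the occasional degenerate fit) and scores the
group-parameter trajectory against each test subject at that subject's best
matching day.

## What the synthetic data do and do not show

The generators produce connected geometric-random connectomes (centroids in
a 120 mm cube, edge density 0.4, ACP uniform on (0.4, 0.95), fiber length =
Euclidean centroid distance) and regular geometries (chain, ring,
hub-and-spoke) for targeted fixtures; cohorts drawn from documented priors
(production U(0.3, 0.9), clearance U(0.1, 0.5), snapshot day
U(2000, 12000), deterministic by default); and voxel tables with a
reference region at Normal(0, sd) and region signals shifted by
$3 \cdot sd \cdot P_i$. Sparser graphs are deliberate: they stagger fiber
arrivals across the simulated decades so that snapshots fall in the dynamic
phase of the epidemic.

Passing tests on these data demonstrate internal consistency — the
simulator realizes the stated equations, the fitting machinery inverts the
simulator, the network statistics behave as the model predicts — and
desk-scale analogues of the qualitative findings (distance-arrival
linearity, hub vulnerability, the value of true connectivity over
degree-preserving nulls). They do not demonstrate anything about real PET
cohorts: synthetic voxels have no spatial autocorrelation or
partial-volume effects, synthetic connectomes have no realistic community
structure, true amplitudes are drawn from the fitting model's own family
(no model misspecification), and cohort-level percentages from the
733-subject study are not reproducible at these sizes.

## Problem sizes and runtimes

The test-suite and acceptance analyses use 8-15 region connectomes,
cohorts of 5-20 subjects, full 18,250-day horizons, 19 null randomizations,
and 40,000-draw bootstrap calibrations. A single full-horizon simulation of
a 10-region connectome takes ~10 ms in the compiled core; a full
per-subject fit (roughly a thousand candidate simulations) takes ~10 s; the
complete acceptance computation runs in a few minutes on one CPU.

## Known limitations

* The ACP matrix is symmetric, so anterograde and retrograde propagation
  cannot be distinguished.
* Production and clearance amplitudes are global per subject; regional
  heterogeneity in these rates is not modeled.
* The four shape constants are fixed, not fitted; subjects are compared
  conditional on them.
* Early-snapshot observations under-determine the production amplitude
  (see above).
* The greedy seed search is not guaranteed to agree with exhaustive
  enumeration on multi-region outbreaks.
* NIfTI image input is not implemented; voxel tables arrive as
  region-labelled TSV.
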