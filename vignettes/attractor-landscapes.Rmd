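---
title: "Individualized neural-mass models and their attractor landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized neural-mass models and their attractor landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindyscapes)
```

## The model

`mindyscapes` fits and analyzes Mesoscale Individualized NeuroDynamics
(MINDy) models: discrete-time neural-mass networks in which each cortical
parcel is one state dimension. One model step (one TR, the fMRI sampling
interval) is

$$x_{n+1} = x_n + W\,\psi_\alpha(x_n) - D \odot x_n,$$

where the effective connectivity $W = W_S + W_1 W_2^{\top}$ is the sum of a
sparse matrix and a rank-$k$ matrix, $D$ is a per-parcel decay, and

$$\psi_\alpha(x) = \sqrt{\alpha^2 + (bx + 0.5)^2} -
  \sqrt{\alpha^2 + (bx - 0.5)^2}$$

is an odd, strictly increasing transfer function bounded in $(-1, 1)$ with a
trainable per-parcel curvature $\alpha$ and fixed shape constant $b = 20/3$.
Because there is no bias term, the vector field is odd, $f(-x) = -f(x)$: the
origin (the data mean, after standardization) is always an equilibrium, and
every non-origin attractor has a mirror image $-x^\ast$.

The scientific question the pipeline addresses is whether resting-state
activity is better described as noise around a single stable mean or as a
nonlinear system with nontrivial attractors. The package answers it
operationally: fit a model per session, enumerate its attractors, test the
attractors' reliability across sessions and people, and probe how one
landscape deforms into another through bifurcations.

## From BOLD observations to training data

`preprocessTimeseries()` applies, in fixed order:

1. **Outlier interpolation** (`interpolateOutliers`): per parcel, frames
   beyond 5 standard deviations from the mean are linearly interpolated
   between the nearest valid neighbours (clamped at the ends). The mean and
   standard deviation are computed once, not re-estimated.
2. **Hemodynamic deconvolution** (`wienerDeconvolve` with
   `canonicalHrf`): Wiener deconvolution with a 30-sample canonical
   double-gamma HRF (response delay 6 s, undershoot delay 16 s, unit
   dispersions, response:undershoot 6, unit peak) and noise-to-signal ratio
   0.02. The filter $\bar H /(|H|^2 + \mathrm{nsr})$ bounds the inverse
   gain, so frequencies where the HRF carries no power are suppressed
   rather than amplified. Deconvolution runs per scanning run to avoid
   boundary artifacts.
3. **Z-scoring** (`zscoreColumns`): each parcel, each run, to mean 0 and
   sd 1. The applied centering/scaling is recorded so ground-truth states
   can be mapped into the standardized coordinates.
4. **Derivative targets** (`buildTrainingPairs`): states $x_n$ paired with
   the two-point smoothed forward difference
   $\hat{\Delta}x_n = (x_{n+2} - x_n)/2$, which cancels Nyquist-frequency
   noise exactly (an alternating series has smoothed derivative 0). Pairs
   never span a run boundary.

## Fitting

`fitMindy()` minimizes

$$J = \tfrac12\|\hat\Delta x - [(W_S + W_1W_2^{\top})\psi_\alpha(x) -
  D\odot x]\|_2^2 + \lambda_1\|W_S\|_1 + \lambda_2\,\mathrm{Tr}(|W_S|) +
  \lambda_3(\|W_1\|_1 + \|W_2\|_1)$$

with $\lambda_1 = 0.075$, $\lambda_2 = 0.2$, $\lambda_3 = 0.05$, by NADAM
on minibatches of 300 samples drawn with replacement, stopping after a
fixed budget of 5000 minibatches. Analytic gradients are used (verified
against central finite differences in the test suite); the L1 subgradient
at exact zeros is taken as 0. After training, `globalRescale()` solves the
two-parameter least-squares problem
$\hat\Delta x \approx p_W\,W\psi_\alpha(x) - p_D\,D\odot x$ in closed form
and folds $p_W, p_D$ back into the parameters ($\sqrt{|p_W|}$ into each
low-rank factor), undoing regularization shrinkage of the overall scale.

Choices the loss itself does not fix:

* **Curvature initialization and regime selection.** $\alpha$ starts at 30
  per parcel, which makes $\psi_\alpha$ effectively linear over the
  standardized data range ($|x| \lesssim 3$). This choice is load-bearing.
  The model has two qualitatively different regimes for representing a
  near-linear conditional mean: a near-linear transfer with moderate $W$,
  or a saturated transfer ($\alpha \approx 1$, $b|x| \gg \alpha$) with $W$
  rescaled to match the *average* slope of $\psi$ over the data. Both fit
  the bulk data about equally well, but the saturated regime's gain at the
  origin, $\psi'(0)$, exceeds its data-average gain by roughly 10%, so on
  stationary noise whose slowest mode has a one-step multiplier near 1 the
  saturated solution tips the origin unstable and fabricates a spurious
  $\pm$ attractor pair at the amplitude where the saturated drive balances
  the linear decay. Initializing in the near-linear regime removes that
  bias; the optimizer still descends into saturation whenever the data are
  genuinely bimodal (planted bistable landscapes are recovered with median
  pattern correlation above 0.98). We verified the effect is not a gradient
  or convergence artifact: gradients match finite differences to relative
  error $10^{-9}$, and quadrupling the batch budget does not rescue the
  saturated initialization on noise data.
* **Optimizer constants.** Learning rate $10^{-2}$, $\beta_1 = 0.9$,
  $\beta_2 = 0.999$, $\epsilon = 10^{-8}$. The learning rate is chosen so
  the curvature can traverse its useful range within the batch budget; at
  $2\times10^{-3}$ the fit is visibly under-converged after 5000 batches.
* **Constraints.** $\alpha$ is clamped below at $10^{-3}$; $D$ is left
  unconstrained in sign. Weights initialize at $N(0, (0.01/\sqrt N)^2)$,
  $D$ at 0.2.

## Attractor landscapes

`classifyLandscape()` integrates the (noise-free) dynamics from many
initial conditions — 1000 frames resampled from the training data for
fitted models, or standard normal draws for interpolated models — for 1600
steps of one TR each, then:

* **Equilibria**: a trajectory has converged when each of its last 10 steps
  changes every coordinate by less than $10^{-6}$ (strictly). Terminal
  states are clustered greedily in input order with a Euclidean threshold
  of 0.1 against cluster *founders*; the founder is the representative.
  Each reported equilibrium is re-verified against the vector field
  ($\|f(x^\ast)\|_\infty < 10^{-5}$).
* **Limit cycles**: a non-converged trajectory is cycling when it entered
  the Euclidean ball of radius 0.5 around its terminal state, left it, and
  re-entered. One period is the segment between the two most recent entry
  events, so its first and last samples sit at the same phase. If no
  recurrence is found the simulation is prolonged, up to 20 times the
  original length, before the trajectory is counted as *unresolved*
  (reported, never silently dropped). Cycles from different trajectories
  are merged when one's terminal point lies within half the recurrence
  radius of the other's orbit, measured as point-to-polyline distance —
  plain sample-to-sample distance fails for fast cycles whose per-step arc
  exceeds the threshold.
* **Ghost attractors**: the slowest point $\arg\min_n \|x_{n+1} - x_n\|_2$
  of each cycle (ties to the lowest index). A landscape with exactly one
  limit cycle gets a symmetric pair of slowest points, because the odd
  symmetry makes a unique cycle self-symmetric.
* **Taxonomy**: the label `"<nFP>FP <nLC>LC"` counts stable equilibria and
  cycles; whether the landscape is exactly one equilibrium at the origin
  (norm below 0.1) is exposed separately, since "globally attractive
  origin" is the trivial-dynamics verdict for the negative controls.
  Models whose trajectories diverge ($|x| > 10^6$) in more than half of the
  initial conditions are flagged `"numerical issues"` and excluded
  downstream.

## Bifurcations between models

`combineDynamics(m1, m2, gamma)` evaluates
$\gamma f_1(x) + (1-\gamma) f_2(x)$ — a dynamics object rather than a
MindyModel, because a convex combination of two MINDy vector fields with
different curvatures is generally outside the parameter family.
`sampleSpectrum()` draws (pair, $\gamma$) combinations within or across
persons and tallies the taxonomies of the combined dynamics from 120
standard normal initial conditions. `mixWeights()` (element-wise parameter
mixing) and `shuffleWeights()` (random permutation of the effective
connectivity entries, stored in the sparse slot since shuffling destroys
low-rank structure) are the corresponding controls.

The analytic companion is the planar saddle-node-on-invariant-circle
normal form (`toySnic`),

$$\dot r = g\,r(1 - r^2), \qquad \dot\theta = \mu - \sin 2\theta,$$

integrated with step 0.01. For $0 < \mu < 1$ it has two pairs of hyperbolic
equilibria on the unit circle where $\sin 2\theta = \mu$ (the
$\arcsin(\mu)/2$ pair stable, the $(\pi - \arcsin\mu)/2$ pair saddles,
enumerated exactly by `snicEquilibria`); for $\mu > 1$ the unit circle is a
limit cycle whose angular speed ranges over $[\mu - 1, \mu + 1]$, so the
period diverges and the slowest points become ghost attractors as
$\mu \to 1^+$. Forward simulation can only discover the stable pair below
the bifurcation; the saddle pair is asserted through the analytic
enumeration. The main text's toy-model properties (two pairs of equilibria
below, one stable limit cycle above, symmetry under state negation) fully
constrain this choice of normal form up to smooth equivalence, but we do
not claim it is identical to any particular published supplement.

## Reliability and clustering

Attractors are compared as anatomical activation patterns.
`patternCorrelation` is the Pearson correlation across parcels; `das` (the
dominant attractor similarity) is its maximum over all cross pairs of two
models' attractors, with equilibria and ghosts pooled. Origin equilibria
are excluded from pattern analyses: the zero vector has no direction, so
its correlation and unit normalization are undefined.

`cosineKmeans` clusters unit-normalized attractors under
$d(x, y) = 1 - \cos\angle(x, y)$ with k-means++-style seeding, 20 restarts,
and centroid re-normalization; an emptied cluster is re-seeded from the
worst-fit point. `instabilityIndex` measures split-half stability: K-means
on one half classifies the other half, the result is compared with K-means
run directly on that half after optimal label matching, averaged over 30
halvings, and normalized by the same cost with uniformly random labels.
The matching is computed exactly on the $K \times K$ confusion matrix by
bitmask dynamic programming ($K \le 10$), which attains the same optimum as
the Hungarian algorithm and is oracle-tested against exhaustive
permutations. `selectK` returns the interior local minima of the
instability curve; $K = 2$ is flagged as the trivial solution that merely
splits each pattern from its mirror image. `varianceDecomposition` reports
the fraction of the attractor matrix's total sum of squares captured by
cluster-by-network cell means.

## The synthetic ground truth

The generator plants low-dimensional normal forms inside full MINDy
parameter sets, so recovery tests exercise the real transfer function:

* **Bistable ("2FP")**: one parcel self-excites with weight
  $w = d\,s/\psi_1(s)$, the exact solution of the fixed-point equation for
  amplitude $s$ (default 1.5); the origin is unstable because
  $w\,\psi'(0) > d$. Remaining parcels are slaved through a random
  coupling column, giving each attractor a distributed anatomical pattern.
* **Limit cycle ("1LC")**: a $2\times2$ rotation block with gain
  $1.3\,w$ and rotation angle 1.2 rad. Small angles are not enough: below
  roughly 0.8 rad the rotated fixed-point equation still has stable
  solutions and the landscape is multistable rather than oscillatory; the
  1.2 rad choice yields a single self-symmetric cycle robustly across
  seeds. "4FP" uses two independent bistable parcels; "2LC" a bistable
  parcel crossed with a cycle block (a product of a two-point attractor
  and a cycle is two cycles). A requested "2FP 1LC" coexistence is *not*
  constructible this way: $\psi$ is odd and concave on $x > 0$, so the
  secant gain $\psi(r)/r$ is maximal at the origin and a block whose origin
  is stable cannot also sustain a distant stable cycle; the constructor
  rejects the label. Every construction is verified by
  `classifyLandscape` and regenerated with the next seed on failure.
* **Observations** (`simulateObservation`): Euler–Maruyama integration with
  per-parcel process noise (default sd 0.3 per step — strong enough that a
  bistable trajectory hops between basins many times per run, keeping the
  run mean near zero and both basins sampled), 100 discarded burn-in
  steps, optional causal HRF convolution, measurement noise (default sd
  0.1), per-run z-scoring. Defaults mirror the acquisition the pipeline
  targets: TR 0.72 s, two runs of 1200 frames per session.
* **Stationary surrogates** (`stationarySurrogate`): common random phases
  per frequency applied to every parcel's Fourier transform within each
  run. This preserves each series' amplitude spectrum bit-exactly and, as
  the phases are shared across parcels, the cross-spectra and covariance
  exactly. One caveat matters for interpreting negative controls: an
  exact-periodogram surrogate is only as Gaussian and mixing as its source
  spectrum is broadband. If the source concentrates its power in a few
  low-frequency bins (e.g. a bistable system that hops rarely), the
  surrogate degenerates toward a few large sinusoids whose arcsine-shaped
  marginals linger near their extremes and genuinely mimic bistable drift.
  The default process noise is chosen so sources mix well within a run and
  the surrogate null actually is the stationary noise it is meant to be.
* **Linear system** (`linearSystemTimeseries`): $x_{n+1} = (I + A)x_n +
  \epsilon_n$ with spectral radius of $I + A$ checked below 1.
* **Cohort** (`makeCohort`): persons $\times$ two sessions; each person
  has a fixed coupling geometry, and a configurable fraction switch
  between "2FP" and "1LC" across sessions while keeping that geometry —
  the infinite-period mechanism by which real session pairs can disagree
  in taxonomy yet agree in anatomy.

## What the tests do and do not show

The synthetic world reproduces the *mechanisms* — bistable and oscillatory
landscapes with distributed anatomical patterns, hemodynamic observation,
session-to-session bifurcation, population-level pattern clusters — at
reduced size ($N = 10$–20 parcels versus 200; 2400 frames versus 4800; one
session pair per synthetic person). It does not emulate head motion,
physiological noise, regional HRF variability, scanner drift, or the 1/f
spectral shape of real BOLD. Passing the suite therefore shows that the
estimator and the landscape analysis are correct and unbiased in the
regimes the model family expresses, not that any particular claim about
human cortex transfers.

Problem sizes used by the test suite and the acceptance script — fits at
$N = 20$, $T = 2400$ with 2000 batches for the negative controls, $N = 10$
with 5000 batches for recovery, 120–300 initial conditions and 1600 steps
per landscape, 30 split-halves per instability point — were chosen so the
distributional claims (rates over 10 seeds) are reproducible on a single
CPU in minutes while staying at the paper-scale ratios of data to
parameters.

## Numerical choices and degenerate inputs

* Divergence is declared at $|x| > 10^6$; diverged trajectories are parked
  and flagged, never mixed into attractor statistics.
* Ties in the slowest-point search break to the lowest index; equilibrium
  clustering ties break to the earliest founder (input order).
* The singular $2\times2$ rescaling system leaves scales at 1 with a
  warning; a zero-variance parcel is an error naming the parcel; an
  all-outlier column cannot occur at the default threshold but is an error
  regardless.
* The toy model keeps the default classification thresholds: with step
  0.01 its convergence and recurrence scales sit comfortably inside the
  equilibrium tolerance and the 0.5 neighbourhood radius on the unit
  circle.
* `linearSystemTimeseries` z-scores per run but leaves zero-variance
  columns unscaled (relevant only for noise-free inputs).

## Known limitations

* Stability is assessed by simulation, not by Jacobian eigenvalues;
  unstable sets and saddles of fitted models are invisible (the toy model's
  saddles are enumerated analytically instead).
* The greedy founder-based equilibrium clustering is order-dependent for
  attractors closer than twice the threshold; the suite checks
  order-invariance only for well-separated landscapes, which is the regime
  the threshold is designed for.
* Cycle merging assumes one period samples the orbit densely enough that
  the point-to-polyline distance is small; extremely slow ghost passages
  with very coarse sampling elsewhere could defeat it.
* `sampleSpectrum` classifies each draw independently; it does not reuse
  endpoint landscapes, so very large spectra are computation-bound.
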