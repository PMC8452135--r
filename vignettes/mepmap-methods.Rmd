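---
title: "Gaussian-process active sampling for TMS motor mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process active sampling for TMS motor mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcranial magnetic stimulation (TMS) motor mapping estimates the spatial
field of motor-evoked-potential (MEP) amplitudes — microvolts of muscle
response as a function of the 2-D stimulation locus on the projected scalp
plane. Conventional protocols stimulate a fixed grid many times and spend
most of their stimuli on null-response territory, because the excitable
representation of a hand muscle is a small, sharply concentrated subregion
of the mapped patch. `mepmap` implements and evaluates, in a closed
simulation loop, sampling strategies that instead choose each next
stimulation locus from the data observed so far.

## Field models

**GP regression.** Observed amplitudes are modelled as
$y_k = \psi(x_k) + \eta_k$ with $\eta_k \sim N(0, \sigma_\eta^2)$ and a
zero-mean GP prior on $\psi$ under the isotropic exponentiated-quadratic
kernel $\kappa(a,b) = s^2 \exp(-\|a-b\|^2 / 2h^2)$. The predictive mean and
variance at a query are the standard conditional-Gaussian expressions with
the noise-augmented Gram matrix $K_{AA} + \sigma_\eta^2 I$. We use the
noise-augmented matrix *everywhere* — in the evidence, the predictive
equations, and every acquisition solve — both for internal consistency and
for conditioning; the evidence is
$y^\top (K+\sigma_\eta^2 I)^{-1} y + \ln|K+\sigma_\eta^2 I| + N\ln 2\pi$
(the $-2\ln$ scale). All three hyperparameters
$(s, h, \sigma_\eta)$ are fitted jointly by maximum marginal likelihood on
log-parameters (L-BFGS-B), because the evidence surface is multimodal, from
multiple starts: a warm start when one exists, two deterministic data-scale
anchors (signal scale at `sd(y)`, bandwidth at the median pairwise distance
and a quarter of it), and seeded log-uniform restarts over
$[10^{-2}, 10^{2}]\times$ the data-scale heuristics. Fits are deterministic
given the seed.

**Warped GP.** MEP amplitudes are non-negative, which a plain GP cannot
guarantee. We fit the GP in a latent space reached through the square-root
warp $z = g(y) = \sqrt{2y}$, whose inverse is $y = g^{-1}(z) = z^2/2$.
Because the warp is fixed, its Jacobian adds a hyperparameter-independent
constant to the evidence and latent fitting is ordinary marginal-likelihood
maximization on $z$. Observation-space moments come from linearizing
$g^{-1}$ at the latent posterior mean ($dy/dz = z$, linearization point
$z_0 = \mu_z$):
$$\mu_y = \tfrac12 \mu_z^2, \qquad \sigma_y^2 = \mu_z^2 \sigma_z^2 .$$
The predictive mean is non-negative by construction, and both
observation-space moments vanish wherever $\mu_z = 0$. We keep the
zero-mean latent prior: far from data the field reverts to $\mu_y = 0$,
which matches the null-response background of a motor map. No second-order
correction is applied, and the latent-variance degeneracy at $\mu_z = 0$
(zero acquisition score in unexplored null regions) is implemented
literally, not mitigated.

## Acquisition criteria

All criteria are greedy one-step rules $\ell^* = \arg\max_\ell \delta_\ell$
over a candidate lattice; ties break to the lowest candidate index for
reproducibility. Scores are recomputed from scratch each iteration — at
budgets of a few hundred points, $O(N^3)$ per step is negligible and
rank-one updates would only add state to audit.

* **GPE** — $\delta_\ell = s^2_{\ell|A}$, the spatial posterior variance.
  Geometry-only: it ignores every observed amplitude, spreads stimuli
  almost uniformly, and drifts to the edges of the region where variance is
  largest.
* **MI** — the ratio of the posterior variance given the selected set to
  the posterior variance given the rest of the candidate universe.
  Historically proposed to avoid the edge bias of entropy; provided for
  completeness and for tests (it converges to GPE-like uniform coverage on
  this problem and is not used in the headline loops). A candidate whose
  complement set is empty scores $-\infty$; a denominator below $10^{-12}$
  raises a degeneracy error.
* **GPE$_\mu$** — conditional variance in *amplitude* space: the same
  kernel form applied to scalar field estimates $\hat\psi$ rather than
  loci. The criterion seeks amplitudes unlike those already sampled (pure
  exploitation, no spatial term). The source never states how the amplitude
  kernel's hyperparameters are chosen, so we use the median heuristic —
  bandwidth = median absolute pairwise difference of the candidate-set
  estimates, signal variance = their sample variance — refreshed every
  iteration; both have small positive floors for the all-equal degenerate
  case.
* **WGPE** — the warped-GP observation-space variance
  $\mu_z^2 \sigma_z^2$: large only where the model expects both high
  amplitude and high uncertainty, giving a built-in
  exploration–exploitation balance.

## Sampling loops

The **greedy entropy loop** iterates score → argmax → query the oracle →
append → refresh, with the field estimate taken from the GP mean
(GPE/GPE$_\mu$) or warped-GP mean (WGPE). The candidate set defaults to a
2 mm lattice over the domain and the initial design to a uniform 6×6
(36-point) lattice; both are configurable. Hyperparameters are refit every
iteration up to 100 samples and every 5th iteration beyond, warm-started
from the previous optimum; between refits the posterior is still
reconditioned on the enlarged training set, so only redundant optimizer
restarts are skipped.

**GPRS** is grid-free: the non-negative warped-GP mean, normalized by
double trapezoidal quadrature on a 0.5 mm lattice, is treated as a
probability density $\hat p(x) = \mu(x)/\int\mu$, and each next locus is
drawn from it by accept–reject with a uniform proposal over the domain
rectangle and envelope constant $1.1\times$ the lattice supremum of
$\hat p$. Density evaluations at proposals use the mean field directly (no
lattice interpolation). While the fitted mean is degenerate — e.g. every
observed MEP is null — the draw falls back to a uniform density and the
fallback is logged, so on a null field GPRS behaves exactly like uniform
random sampling. The proposal loop is guarded at $10^6$ proposals.

Randomness is organized as one root seed per run with separate derived
streams for density draws and fit restarts, kept in private RNG state so
library calls never disturb the caller's generator; identical configs and
seeds reproduce byte-identical manifests and metrics for every strategy.

**Baselines.** UGRID lays the $\lceil\sqrt N\rceil$-per-side
boundary-to-boundary lattice truncated to $N$ in row-major order; URAND
draws i.i.d. uniform loci. The conventional GRID protocol (7×7 sites, 1 cm
pitch, 6 repeats = 294 stimuli) and RAND protocol (4 corners + hotspot +
289 seeded random sites) are provided as deterministic constructors;
repeats at a GRID site are averaged into one per-site amplitude before
model fitting (the aggregation rule is not specified in the mapping
literature we follow; the raw stimuli are kept in the run record).

## Ground truth

**Synthetic fields** are Gaussian-bump mixtures over a constant background,
queryable anywhere, with closed-form volume $2\pi A s_1 s_2$ per bump used
as a quadrature check. The default preset is a single bump of peak
3000 µV and isotropic spread 0.4 cm centered at (2.6, 3.4) cm in a 6×6 cm
domain: with the 50 µV response criterion its excitable region covers
≈11% of the patch. The spread was set from the excitable-area condition —
a focal intrinsic-hand-muscle representation occupying ~10% of the mapped
patch at a physiological peak amplitude — since at such a peak a broader
(e.g. 0.7 cm) spread would push the supra-threshold area to ~35% of the
domain and no longer represent a sparse map. What the preset does *not*
emulate: trial-to-trial MEP variability (available separately as a
multiplicative lognormal wrapper with median factor 1), multi-peaked or
anisotropic representations (expressible via the spec but not default),
and any 3-D scalp geometry. Passing tests on this preset therefore
demonstrate the closed-loop machinery and the exploration–exploitation
ordering of the criteria, not performance on physiological noise or
complex topographies.

**Surrogates from recorded samples** follow a two-step construction:
scattered samples are first interpolated onto a 3.75 mm lattice, negatives
clipped to zero; a warped GP is then fitted to the lattice and its
predictive mean becomes the deterministic oracle (predictive variance is
available for diagnostics but not added as noise). For the scattered
interpolation we use a thin-plate-spline radial-basis interpolant, exact at
the sample loci, with loci outside the convex hull of the samples filled
with 0 — extrapolating MEP amplitudes is unsafe, and null response is the
physiologically sensible fill. A coverage error is raised when more than
10% of lattice nodes fall outside the hull.

## Metrics

Reconstruction error is
$\mathrm{NMSE}(\psi, \hat\psi) = \|\psi - \hat\psi\|_2^2 / \|\psi\|_2^2$
with both fields evaluated on a dense 0.5 mm test lattice. Map volume and
area use double trapezoidal integration (area integrates the
supra-threshold indicator; the default 50 µV threshold is the standard MEP
response criterion used for resting-motor-threshold determination, and is
configurable). The center of gravity is the amplitude-weighted centroid
over lattice nodes. The ROI fraction of a run is the fraction of its
stimulation loci whose *oracle* value exceeds the threshold; by default the
initial design is excluded so the figure reflects only the loci the
strategy chose (both modes are exposed, since either reading of "sampled
stimuli" is defensible).

## Numerical choices

* Gram matrices always receive a jitter of $10^{-8} s^2$ on the diagonal
  before Cholesky factorization; solves go through the factor, never an
  explicit inverse.
* Locus coincidence (duplicate detection in candidate bookkeeping) uses a
  $10^{-6}$ cm tolerance: squared distances computed by the usual
  inner-product expansion carry ~$10^{-14}$ cancellation noise for
  identical rows, while genuinely distinct loci are $\ge$ 2 mm apart on the
  default candidate lattice.
* Posterior variances are clipped below at 0 (they can go negative by
  rounding at interpolation-exact points).
* `warp()` clips inputs in $[-10^{-9}, 0)$ µV to 0 — interpolation float
  dust — and rejects anything lower as corrupt data.
* The accept–reject envelope uses a 1.1 safety factor over the lattice
  supremum; a proposal batch whose density exceeds the envelope aborts
  rather than silently truncating.
* With fewer than 3 distinct training loci (e.g. a single-point initial
  design), marginal-likelihood fitting is ill-posed and the loop falls back
  to domain-scale defaults (bandwidth = mean side length / 6, signal scale
  from the data magnitude) until enough loci accumulate.

## Problem sizes

The test suite and the results script run the closed loops at a budget of
100 stimuli with a 36-point initial design on the default synthetic bump,
with 3–10 repetitions for the stochastic strategies, and verify the dense
linear-algebra identities on instances of up to 25 candidates — sizes at
which brute-force oracles are exact and the full suite completes in a few
minutes on a laptop core. The closed-form, distributional
(n = 50,000 draws for uniformity, n = 10,000 for the bump mean) and
recovery (n = 200, 10 seeds) checks use the sample sizes stated alongside
each test.

## Known limitations

* The WGPE score ring $\mu_z \sigma_z$ sits at the skirt of a sharp bump;
  on very focal fields part of that ring lies outside the 50 µV contour, so
  WGPE's in-ROI fraction is lower there than on the broad, noisy maps of
  real subjects, while still several-fold above the uniform baselines.
* GPE$_\mu$ inherits its known failure mode: with a dense candidate grid it
  can exploit small amplitude neighbourhoods while ignoring unexplored
  space.
* The surrogate's thin-plate interpolation is one defensible dialect of
  scattered-data interpolation; others (Delaunay-based piecewise cubics)
  would differ slightly near the hull.
* MI is implemented to its definition but costs a dense solve per
  candidate per step; it is not meant for large candidate sets.
* All geometry is the projected 2-D scalp plane; no head model, coil
  orientation, or stimulation intensity enters the model.
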