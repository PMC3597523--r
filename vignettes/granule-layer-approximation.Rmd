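---
title: "Piecewise-linear approximation with granule-cell ramp units: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise-linear approximation with granule-cell ramp units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grcpl)
```

## The model

`grcpl` implements a static rate model of the spinocerebellar pathway and
the cerebellar cortex.  Three anatomical stages map onto three mathematical
objects:

1. **Projections** (`projection_set`).  Spinocerebellar neurons mix raw
   sensorimotor variables linearly before they reach the cerebellum.  Each
   mossy-fibre channel therefore carries one linear *projection* of the raw
   input $x \in \mathbb{R}^d$: a unit vector $\alpha_k$ and the scalar
   signal $\alpha_k^\top x$.

2. **Granule cells** (`granule_population`).  A granule cell is a ramp
   unit: below its threshold it is silent, above it the firing rate grows
   linearly.  Unit $j$ assigned to projection $k$ outputs
   $g_j(x) = \max(0,\; v_j\,\alpha_k^\top x - \theta_j)$,
   where $\theta_j$ abstracts the distance from resting potential to spike
   threshold (set biologically by tonic, mostly Golgi-cell, inhibition) and
   $v_j$ is the lumped mossy-fibre gain.  A redundant population sharing one
   projection but spreading its thresholds tiles the projected axis with
   rectifier kinks.

3. **Purkinje readout** (`purkinje_readout`).  The Purkinje cell modulates
   a spontaneous baseline $p_0$ linearly in its granule inputs,
   $p(x) = p_0 + \sum_j w_j\, g_j(x)$, with $w_j$ of either sign (negative
   weights travel through molecular-layer interneurons).

Along any straight line through input space $p(x)$ is a continuous
piecewise-linear (PL) function and every granule threshold is one potential
knot.  With $N$ uniformly spread knots the PL approximation error of a
smooth one-dimensional function falls like $1/N^2$; the package verifies
this empirically (doubling knots must shrink the sine-fit RMSE to below
0.3 of its value).

## Targets and grids

The approximation benchmark is the set of non-linear interaction terms of
the inverse dynamics of a planar two-joint arm, reduced to their
interaction structure (all constant coefficients removed):

| name | form | variables |
|------|------|-----------|
| `inertial2d` | $\ddot\theta\,\cos\theta$ | acceleration, angle |
| `centripetal2d` | $\dot\theta^2\,\sin\theta$ | velocity, angle |
| `product2d` | $\dot\theta_e\,\dot\theta_s$ | two velocities |
| `coriolis3d` | $\dot\theta_e\,\dot\theta_s\,\sin\theta$ | two velocities, angle |

Angles cover one full period $[-\pi, \pi]$ so that every trigonometric
feature is seen; velocities/accelerations are dimensionless on $[-1, 1]$
(the coefficients being stripped, the scale is arbitrary; a symmetric unit
interval keeps the lattice symmetric under negation).  Evaluation grids are
equidistant tensor lattices including both endpoints; the defaults are
21 points per axis in 2-D (441 points) and 11 in 3-D (1331 points) — dense
enough that the grid RMSE tracks the continuous one, small enough that a
3-D objective evaluation stays well under a millisecond.  The error
functional is the grid RMSE, reported relative to the *maximum RMSE*: the
RMSE of the all-zero predictor, so 100% means "no better than silence".

These choices matter for one structural fact the analyses lean on: on a
symmetric lattice with full-period angles, every term that is odd in each
of its variables (the pure product, the inertial coupling) is orthogonal to
all additive functions $f(x_1) + g(x_2)$.  Raw, non-recombined inputs can
only produce additive PL surfaces, so their best fit of those terms is
exactly the zero function — relative RMSE 100%.  This is the raw-signal
degeneracy the package's main printed-number check reproduces.

## Fitting

All fits exploit that the objective is linear in $(p_0, w)$: at every
candidate setting of the non-linear parameters the readout is solved in
closed form (minimum-norm least squares via the SVD; the fast inner loops
use pivoted QR, whose residuals are identical).  This *variable projection*
removes the largest, exactly solvable block of unknowns from the search —
the historical difficulty of simplex search over the full parameter vector
motivates it.

* `fit_fixed_directions()` — directions frozen; thresholds start equally
  spaced but strictly inside the projected value range (a knot at the
  projected maximum would belong to a silent unit whose Jacobian column is
  zero — the optimizer could never revive it) and are refined
  by a Levenberg–Marquardt loop on the residual vector with a
  finite-difference Jacobian (cap `max_lm_iterations`, default 100;
  convergence when the relative cost improvement falls below `tolerance`,
  default 1e-8).  Only improving steps are accepted, so the result can
  never be worse than its initialization.  Granule gains are fixed at 1:
  gain magnitude is redundant with threshold and weight scale, and removing
  a non-identifiable parameter is free accuracy.
* `fit_joint()` — directions free.  They are parameterized by angles (one
  per direction in 2-D, azimuth/polar pairs in 3-D) so unit norm holds by
  construction.  Nelder–Mead searches angles plus thresholds (readout
  solved inside), capped at `max_iterations` per run; the incumbent is then
  perturbed by Gaussian noise of scale `restart_perturbation` (default 0.1)
  and re-optimized `restarts` times, keeping the best.  The reported RMSE
  is an upper bound on the global optimum — there is no global guarantee.
  The simplex start is the best of `n_screen` random direction sets scored
  cheaply with uniform thresholds; that good-enough directions occur among
  random ones is itself one of the findings the experiments quantify.

Degenerate cases are handled without drama: rank-deficient granule designs
(e.g. a threshold at the projected maximum, whose unit never fires) get the
minimum-norm readout; a non-finite objective is flagged
(`converged = FALSE`) rather than raised; equal-RMSE incumbents resolve to
the first found.  Every result records its seed, and all experiment seeds
are pure functions of a master seed (`derive_seed()`), so any run replays
bit-identically.

## What the experiments establish — and what they cannot

`run_random_projection_experiment()` fits each term many times with
directions drawn uniformly from the sphere and summarizes the relative-RMSE
distribution per projection count (box = quartiles, centre line = mean,
whiskers = 1.5 IQR).  `run_grc_sweep()` traces the best joint fit against
the granule budget $N$, warm-starting each larger budget from the padded
smaller incumbent so the curve is monotone by construction.
`capacity_report()` is the closed-form curse-of-dimensionality arithmetic:
$10^{10}$ granule cells spread over a 20-dimensional input lattice afford
$10^{10/20} \approx 3.16 \to 3$ knots per dimension, and holding that
resolution while adding two dimensions costs $10^{11}$ cells.

Three structural findings recur.  Moving from two to three random
projections improves every 2-D term substantially.  For the 3-D Coriolis
term, random directions — even many of them — do not reach the accuracy of
optimized ones.  And the terms differ qualitatively in how many projections
they *need*: the pure product is exactly two-ridge representable
($v_1 v_2 = ((v_1+v_2)^2 - (v_1-v_2)^2)/4$, realized by any mirror pair of
directions, of which the ±45° diagonals are one point on a continuum), the
inertial coupling can be approximated arbitrarily well at $q=2$ by a
nearly-parallel pair (a finite-difference construction
$g(\theta + \epsilon a) - g(\theta) \approx \epsilon\, a\, g'(\theta)$ —
optimal two-projection fits visibly "overlap"), but the centripetal term
cannot: its analogous construction
$[g(\theta+\epsilon v) + g(\theta-\epsilon v) - 2g(\theta)]/\epsilon^2$
needs the pure-angle ridge $-2g(\theta)$ as a *third* projection.
Accordingly the two-projection centripetal fit plateaus (about 6–30%
relative RMSE in our sweeps) no matter how many granule cells are added,
while three projections reach about 2% — the package's plateau acceptance
test runs on this term for exactly this reason.

The synthetic-target generator emulates noise-free, coefficient-free
interaction terms on ideal lattices.  It does not emulate sensor noise
(`add_noise()` exists as a fixture but enters no reference analysis),
realistic torque magnitudes, trajectory-correlated sampling of the input
space, or any temporal/spiking structure.  A green test therefore
establishes properties of the approximation geometry, not of a
biophysical simulation.

## Reduced-scale defaults

Published-style runs use 100 repetitions per box and generous optimizer
budgets.  The packaged tests run at desk scale — 20 repetitions, 3
restarts, simplex capped at 2000 iterations per restart — which preserves
every ordinal claim while keeping the suite in minutes; the single
exception is the "worst single random projection reaches 100%" check,
which needs the full 100 draws because it is an extreme-value statistic.
The command-line interface exposes `--full-scale` to restore the published
scale.

## Known limitations

* Joint optimization is derivative-free and local; different seeds can land
  on different near-optima (the restarts and screening mitigate, not
  eliminate, this).
* Direction parameterization by angles is limited to 2-D and 3-D inputs,
  which covers every target here.
* The capacity arithmetic treats granule cells as freely placeable lattice
  knots; it is bookkeeping, not a circuit model.
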