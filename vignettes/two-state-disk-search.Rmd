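---
title: "Two-state active-particle search on a disk: model, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state active-particle search on a disk: model, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disksearch)
```

## The model

`disksearch` simulates a minimal model of a sperm cell searching a bounded
two-dimensional area: an active particle that moves at constant speed
$v_0$ while its heading $\theta$ diffuses,

$$\dot{\mathbf u} = v_0\,(\cos\theta, \sin\theta), \qquad
  \dot\theta = \sqrt{2 D_\theta}\,\xi(t),$$

with $\xi$ unit white noise.  Motion is overdamped (low Reynolds number);
there is no inertia, no translational noise, and no chirality.  The
particle starts at the center of a disk of radius $R$ with a uniformly
random heading and is absorbed on first contact with the rim — the search
ends, successfully or not, when the searcher leaves the area.

The single dimensionless group that controls the geometry of the path is
the persistence length $\ell_p = v_0 / D_\theta$, the contour distance over
which heading correlations decay by $1/e$:
$\langle\cos\Delta\theta(\ell)\rangle = e^{-\ell/\ell_p}$.  On scales far
beyond $\ell_p$ the walk is an ordinary random walk: it can be pictured as
a freely jointed chain with Kuhn length $\ell_k = 2\ell_p$ ($L = N\ell_k$,
$\langle S^2\rangle = N\ell_k^2$), and it diffuses with
$D = v_0^2 / (2 D_\theta)$.

Sperm are observed to switch irreversibly from fairly straight swimming to
tight, vigorously turning motility ("hyperactivation").  The package
models this as a two-state process in which $D_\theta$ jumps from a small
value $D_{\theta,1}$ to a larger $D_{\theta,2}$, under one of three
policies (`switch_policy()`):

* **constant** — no switch (the single-state baseline);
* **rate** — the switch occurs at an exponentially distributed time with
  rate $k$ (an internal, clock-like trigger);
* **positional** — the switch occurs when the radius $r = r_s$ is first
  crossed (an external, position-reading trigger).

Search quality is judged by how evenly the disk is covered: the disk is cut
into a central circle and 19 annuli of width $R/20$, each trajectory's
dwell time per region is recorded, and the ensemble-mean dwell time per
unit area $\Delta T/\Delta A$ is compared across regions.  The summary
statistic is the relative standard deviation (std/mean) of the 20
densities (`coverage_uniformity()`): 0 means perfectly uniform coverage.

## Reference parameterisation

The reference experiments all use $R = 1$, $v_0 = 1$, $\Delta t = 10^{-3}$
and 5000 searchers (1000 for the diffusive-limit run); these are the
package defaults and the conditions reproduced by `cmd_reproduce()` and by
`scripts/acceptance.R`.  The baseline searcher has $D_\theta = 2$
($\ell_p = 1/2$).  The two-state searchers start at
$D_{\theta,1} = 0.67$ ($\ell_p \approx 1.5$) and end at
$D_{\theta,2} = 6.0$; the factor 9 between the two values makes the final
Kuhn length one-ninth of the initial one, and the baseline $D_\theta = 2$
is their geometric mean.  The rate protocol uses $k = 2$, which places the
switch on average near $r = 1/2$ (the mean run length before switching is
$v_0/k = 1/2$); the positional protocol switches exactly there.

One algebraic note on the factor 9: the outer half-radius of the disk
holds three times the area of the inner part, motivating three times the
contour length there at the same end-to-end reach.  With
$\langle S^2\rangle = L\,\ell_k$, equal reach at $3L$ strictly requires
$\ell_k \to \ell_k/3$, i.e. $D_{\theta,2} = 3\,D_{\theta,1}$; the
reference parameterisation nevertheless uses the stronger factor 9
($\ell_k/9$), and the package follows that parameter choice rather than
the back-of-envelope argument.  Nothing downstream depends on the
motivation: the statistics are computed from the realised trajectories.

Under these conditions the package reproduces the reference statistics:
escape time rising from about 1.8 to about 3.1 (roughly 70% longer) and the
relative standard deviation falling from about 1.3 to 0.98 (rate) and 0.94
(positional) — a ~25% more uniform search bought with a longer stay in
the domain.

## Numerical scheme and its conventions

The integrator is explicit Euler–Maruyama with $\Delta t = 10^{-3}$ by
default.  Within a step the displacement uses the *pre-step* heading and
has length exactly $v_0\Delta t$; the heading then receives a Gaussian
increment of variance $2 D_\theta \Delta t$.  The opposite order would be
equally consistent at $O(\Delta t)$; fixing one makes runs reproducible
bit-for-bit.  Other conventions worth knowing:

* **Absorption** is detected at the first step end-point with $r \ge R$;
  the crossing is not interpolated, so escape times carry an $O(\Delta t)$
  bias, far below the sampling error of the reference ensembles.
* **Dwell binning** credits each step's full $\Delta t$ to the region
  containing the step's start point.  A step (length $10^{-3}$) rarely
  crosses a region boundary (width $0.05$), so any attribution convention
  agrees to about one part in $10^3$.  This convention makes dwell time
  exactly conservative: per trajectory, region dwell times sum to the
  escape (or censoring) time, which the tests assert to rounding.
* **Rate-mode switching** draws the exponential waiting time exactly, once,
  at trajectory start.  Per-step Bernoulli($k\Delta t$) trials are offered
  behind `rate_method = "bernoulli"` for comparison; they are biased at
  $O(\Delta t)$.
* **Censoring**: a trajectory still inside the disk at `t_max` (default
  1000, far beyond all reference mean escape times) is returned with
  `absorbed = FALSE` and a warning; censored trajectories are excluded
  from escape-time means but keep their dwell contribution up to the
  censoring time.
* **RNG**: each trajectory runs on an independent substream derived from
  (seed, index) via splitmix64-seeded `mt19937_64` with Box–Muller
  normals.  Ensembles are therefore reproducible and independent of
  execution order, and trajectory $i$ can be re-simulated alone with
  `simulate_trajectory(..., traj_index = i)`.
* **Units**: everything is dimensionless with $R = 1$, $v_0 = 1$ as
  reference scales, but no function assumes those values.

## Persistence-length estimation

`tangent_correlation()` estimates
$\langle\cos\Delta\theta(\ell)\rangle$ over non-overlapping segments of
length $\ell$ along the contour (overlapping windows are available and
estimate the same quantity with correlated samples).
`estimate_persistence_length()` fits $\log$ correlation against lag by
least squares through the origin — the correlation is exactly 1 at zero
lag — using only the lags before the correlation first decays to 0.1.
Beyond that point the estimates are sampling noise around zero; including
them would destroy the log-linear fit, and a fixed threshold keeps the
estimator free of per-dataset tuning.  Default lags are log-spaced so the
decaying region is resolved whatever the (unknown) persistence length.  On
simulated paths of contour length 2000 the estimator recovers
$\ell_p = v_0/D_\theta$ within a few percent for
$D_\theta \in \{0.67, 2, 6\}$.

For externally recorded tracks (`read_tracks()`, table of
`track_id, t, x, y`), headings are not observed; `resample_track()`
interpolates the path to uniform arc-length spacing and differentiates.
These chord headings are slightly smoothed relative to the true tangent,
which inflates the shortest-lag correlations; on tracks much longer than
$\ell_p$ the through-origin fit is insensitive to this, but estimates from
short tracks (contour $\lesssim 10^3$ steps) should be treated as
$\pm 15\%$.  A perfectly straight track yields no measurable decay; the
estimate is reported as a lower bound (`Inf` with a `lower_bound`
attribute, "≥ contour length" in the CLI) rather than a number.

## Diffusion theory and the finite-volume solver

For $\ell_p \ll R$ the radial density obeys
$\partial_t P = D(\partial_r^2 + r^{-1}\partial_r)P$.  The package exposes
the closed-form results used to interpret the simulations: the free-space
spreading Gaussian and its $\sqrt{4Dt}$ growth; the effective outward
drift $2D/r$ of free diffusion and the resulting uniform coverage density
$1/(4\pi D)$; the near-rim drift $D/(R-r)$, independent of the local
density slope; the near-rim dwell density $(R-r)/(2\pi D r)$ whose slope
magnitude at the rim is $1/(2\pi D R)$; and the exact expected occupancy
$u(r) = \ln(R/r)/(2\pi D)$ of diffusion released at the center, whose
integral is the mean exit time $R^2/(4D)$.  The classic image-charge
construction (negative image at $r = 2R$) does *not* satisfy the absorbing
condition in 2D; `image_method_residual()` exposes the non-zero rim
residual as a demonstration.

`solve_radial_fpe()` discretises the radial equation in conservative
finite-volume form: cell-averaged densities, a zero-flux face at $r = 0$
(which absorbs the $1/r$ coordinate singularity without point-evaluating
the drift), an absorbing outer node, and unit initial mass in the
innermost cell standing in for the $\delta(r)/(2\pi r)$ release.  Time
stepping is backward Euler — unconditionally stable and
positivity-preserving — with a geometrically growing step (defaults
$10^{-7} R^2/D$ initial, $2.5\times10^{-4} R^2/D$ cap, growth 1.02): the
delta release needs tiny early steps while the slow late-time relaxation
(slowest mode $\sim R^2/(5.78 D)$) tolerates large ones.  Integration
stops when the surviving mass falls below $10^{-6}$.  At the default 400
cells the time-integrated occupancy matches $u(r)$ within 0.3% on
$r > 0.1R$ and the mean exit time within 0.05%; grid-refinement
convergence is part of the test suite, which also documents that beyond
about 100 cells the spatial error drops below the $\sim0.25\%$
time-integration floor.

## What the generator emulates, and what it does not

The synthetic trajectories realise exactly the model above: constant
speed, Gaussian heading increments, irreversible one-way switching,
absorbing rim.  Real sperm tracks differ in ways the model deliberately
omits: chirality (many observed tracks curl), speed variability and
jitter, sperm–sperm and sperm–wall hydrodynamic interactions, wall
accumulation and sliding, 3D excursions, and measurement noise in the
track coordinates.  Tests passing on synthetic data therefore validate
the implementation and the model's internal consistency — not the claim
that any particular cell follows this law.  The track-import path
(`cmd_estimate_lp()`) applies the same estimator to real data, where the
chord-heading caveat above applies.

## Known limitations and deliberate scope

* The two-state searcher's occupancy has no closed-form theory here; the
  diffusion results apply to the single-state, small-$\ell_p$ limit.
* The finite persistence length leaves a transport boundary layer at the
  absorbing rim that zero-$\ell_p$ diffusion theory cannot capture: the
  effective absorbing plane sits roughly $0.7\,\ell_p$ outside the rim, so
  at $D_\theta = 200$ ($\ell_p = 0.005$) the simulated dwell density in
  the outermost annulus exceeds $u(r)$ by about 14% (and the fitted
  outer-annulus slope exceeds $1/(2\pi D R) = 63.7$ by a few percent,
  landing near 68).  This is physics, not a numerical defect: simulation
  and solver agree wherever the boundary layer is negligible
  ($r \lesssim 0.9R$, agreement ~1%).
* Mean escape times at the reference ensemble size (5000) carry a
  sampling error of roughly $\pm 0.03$; reported reference values are
  reproduced within that spread, not digit-for-digit.
* The solver is strictly radial; no general 2D solver, and no absorbing
  Green's function for off-center releases.

## Problem sizes

The reference reproductions simulate 5000 trajectories per unit-disk
protocol ($\sim 10^7$ Euler steps each, a few seconds of CPU) and 1000
trajectories at $D_\theta = 200$ ($\sim 10^8$ steps, under ten seconds).
Persistence-length checks use single free paths of contour length
2000–3000.  The test suite's property checks run the same sizes and
complete in about a minute on one core.
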