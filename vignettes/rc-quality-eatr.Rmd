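---
title: "Scoring reaction-coordinate quality from biased kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring reaction-coordinate quality from biased kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatr)
```

## The model

A metadynamics-style run deposits a history-dependent bias $V(s,t)$ along a
collective variable (CV) $s$. When the CV resolves the true reaction
coordinate (RC), the escape rate at time $t$ is boosted by the full
Boltzmann factor of the bias; when it does not, only part of the bias is
felt by the transition. The package models the biased hazard as

$$k(t) = k_0\, f(t), \qquad
  f_{\mathrm{EATR}}(t) = e^{\beta\gamma V(s(t),t)}, \qquad
  f_{\mathrm{KTR}}(t) = e^{\beta\gamma V_{\max}(t)},$$

with $\beta = 1/k_BT$, $k_0$ the unbiased rate, and $\gamma \in [0,1]$ the
fraction of the bias that is kinetically effective: $\gamma = 1$ is a
perfect RC (the model then reduces exactly to the iMetaD acceleration
picture), $\gamma = 0$ a bias orthogonal to the transition. KTR replaces the
instantaneous bias with its running maximum $V_{\max}(t)$; for a
monotonically growing bias the two coincide, and KTR dominates whenever the
experienced bias dips. The survival function is
$S(t) = \exp\!\big(-k_0 \int_0^t f\,dt'\big)$, and an ensemble of runs with
transition times $t_i$ (or censored at $t_\max$) has log-likelihood

$$\ell(k_0,\gamma) = \sum_{\text{trans}}\big[\log k_0 + \log f(t_i)
  - k_0 F(t_i)\big] - \sum_{\text{cens}} k_0 F(t_{\max}),
  \qquad F(t) = \int_0^t f\,dt'.$$

Censoring is first-class: a run that never transitions still constrains the
fit through its survival factor, and with zero censored runs the likelihood
reduces to the textbook uncensored form. Real biased campaigns truncate
runs, so this matters in practice even though it costs nothing when unused.

### Averaging conventions

The overbars in the KTR/EATR rate definitions denote averages over the
simulation ensemble. Two conventions are implemented:

* `per_trajectory` (default): each run carries its own hazard
  $f_i(t) = e^{\beta\gamma V_i(t)}$. This yields a well-defined likelihood
  for heterogeneous bias histories and is exactly self-consistent with the
  synthetic generator below.
* `ensemble_mean`: runs are pooled,
  $f(t) = \overline{e^{\beta\gamma V_i(t)}}$ (EATR) or
  $e^{\beta\gamma \overline{V_{\max,i}(t)}}$ (KTR), on a common grid. A
  run's bias is held frozen at its last recorded value after the run ends,
  since bias deposition stops at the transition; the post-transition
  convention is otherwise undefined and freezing is the least-action
  choice.

The two conventions agree closely when all runs share one bias schedule.
They differ materially on metadynamics data, where the instantaneous bias
fluctuates with the walker's position: at the transition instant the walker
sits in the (deliberately unbiased) transition region, so the
per-trajectory density term $\log f_i(t_i)$ systematically under-credits
the bias and pulls $\hat\gamma$ down. The pooled convention averages over
runs still residing in the filled well and is the appropriate choice for
hill-based data; the package's own Langevin analyses therefore use
`ensemble_mean`, while `per_trajectory` remains the default for
schedule-driven data.

### Estimation

For each $\gamma$ on a dense grid (step 0.01) the free-$k_0$ maximum is
available in closed form, $k_0(\gamma) = n_{\text{trans}} / \sum_i
F_i(t_{\text{obs},i})$, so $\gamma$ is profiled on the grid and refined by
bounded local optimization. The grid-first search is deliberate: when
$\beta V_{\max}$ is small the profile is extremely flat near $\gamma = 1$,
and a pure gradient method can silently wander. Estimates landing on 0 or 1
are reported with a `boundaryHit` flag, never clipped; an ensemble with no
bias at all leaves $\gamma$ unidentifiable, which is flagged rather than
errored. Holding $k_0$ fixed (e.g. at an experimental value) removes the
strong $\gamma$–$k_0$ likelihood correlation and visibly lowers the variance
of $\hat\gamma$ — the package's tests assert this directly.

Uncertainties come from a trajectory-level bootstrap (resampling whole
runs, since transition times and bias histories are paired), with 2.5/97.5
percentiles after refitting each replicate; replicates with zero
transitions are skipped and counted. A curvature-based standard error from
the profile log-likelihood is reported alongside; the bootstrap is the
default interval.

### The Poisson/KS diagnostic

Rescaled transition times $\alpha_i(t_i)\,t_i$ of a well-behaved iMetaD
ensemble are exponential. `fitPoissonCDF()` fits their empirical CDF to
$1 - e^{-t/\tau}$ by least squares (the sample-mean MLE is reported
alongside, with a warning when the two disagree by more than 10 %) and runs
a two-sided KS test against $\mathrm{Exp}(\hat\tau)$. Because $\hat\tau$ is
estimated from the same data the plain p-value is conservative
(Lilliefors-type); a parametric-bootstrap p-value is available via
`nBootKS`.

### Moment-based predictors

Isolating $\gamma$ in the EATR formalism gives two closed-form predictors
from ensemble moments (see `predictGamma()`): prediction 1,
$1 - \log(k_0(\bar\tau_{\text{accel}} - \mathrm{cov}(t,\alpha))) /
\log\bar\alpha$, and prediction 2, which drops the covariance. Conventions:
$\bar\alpha$ is the mean of $\alpha_i(t_i)$ over transitioned runs (the
quantity defined by the iMetaD average), and the covariance uses population
normalization (denominator $N$), both configurable. Out-of-range values are
returned unclipped with a flag — they are a useful symptom of a
misspecified $k_0$.

A caveat the package's own experiments expose: the two predictions overlap
only when $\mathrm{cov}(t,\alpha) \ll \bar\tau_{\text{accel}}$. Under a
single deterministic monotone ramp shared by all runs, $\alpha_i(t_i)$ is a
deterministic increasing function of $t_i$, so the covariance is
intrinsically a 10–15 % fraction of $\bar\tau_{\text{accel}}$ and the two
predictions differ by 0.03–0.05 in $\gamma$ units (prediction 1 being the
more accurate). Overlap to better than 0.02 should be expected only when
bias histories vary run-to-run in a way that decouples $\alpha_i$ from
$t_i$ — e.g. genuinely stochastic hill placement — not for ramp-driven
ensembles.

## The synthetic generators

### Hazard inversion (time rescaling)

`sampleTransitionTimes()` draws $u \sim \mathrm{Exp}(1)$ per run and solves
$k_0\int_0^t e^{\beta\gamma_{\text{true}}V(t')}dt' = u$ on the recording
grid, emitting the full $V(t)$ exactly as real data would contain it. The
cumulative hazard uses the same trapezoid rule (on the exponentiated
integrand, accumulated in log space) as the fitting code, with the bias
linearly interpolated inside the bracketing interval; generator and
estimator are therefore consistent to root-finding tolerance
($10^{-9}$ relative), and parameter recovery is a genuine end-to-end check
rather than a quadrature comparison. Runs whose hazard does not reach $u$
by $t_{\max}$ are right-censored there.

Reference study conditions, fixed once and used throughout the tests and
the acceptance script: a linear ramp reaching $\beta V = 15$ at
$t_{\max} = 1000$ time units, $k_0 = 10^{-4}$ inverse time units, ensembles
of 100–200 runs, 20 seeded replicates. The ramp endpoint and rate pin the
identifiability scale ($\mathrm{sd}(\hat\gamma) \approx 0.01$–0.03 per
ensemble); making the ramp end coincide with the censoring horizon means
the $\gamma_{\text{true}} = 0$ construction is heavily censored
(about 90 %), exactly as an orthogonally-biased campaign would be, and the
censoring-aware likelihood still localizes $\gamma$ near 0.

### Langevin double well with rotatable CV

`langevinMetad()` integrates overdamped Euler–Maruyama dynamics (unit
friction) on $U(x,y) = h\,(x^2-1)^2 + y^2/2$ and deposits Gaussian hills
along $s = x\cos\theta + y\sin\theta$ every `pace` steps; $\theta$ dials RC
quality continuously from perfect (0°) to orthogonal (90°). Overdamped
dynamics is the simplest engine exhibiting rare-event phenomenology — the
barrier height, not inertia, sets the timescales. Well-tempering is off by
default (the analysis needs $V(t)$, not a converged free-energy surface); a
bias factor is available for realism. Defaults: barrier $h = 8\,k_BT$,
hills 0.5 × 0.2, pace 500 steps of $dt = 0.002$, 16 runs of at most 600
time units, commitment at $x = 1$, recording every 50 steps (stride
decouples storage from $dt$; pace-scan analyses use stride 250, which at
these hill widths loses nothing the fits can see). The unbiased reference
rate is estimated by brute-force first-passage sampling below $8\,k_BT$ and
by the Kramers high-barrier approximation
$\sqrt{U''_{\min}|U''_{\text{top}}|}/(2\pi)\,e^{-\beta h}$ at and above it;
the record always states which method produced it. Per-run RNG streams are
derived from one master seed by a fixed counter scheme, so ensembles are
reproducible and runs independent.

What the toy system emulates: bias-driven acceleration, RC-quality-dependent
$\gamma$, deposition-pace effects, censoring. What it does not: multi-state
kinetics, diffusion anisotropy along the RC, the 10–12 decades of
acceleration of protein–ligand systems (the ladder here spans 3–5), or
hidden slow modes other than the single orthogonal $y$. Passing tests on it
demonstrate estimator correctness under the model's own assumptions, not
transferability to any particular molecular system.

## Numerical choices

* All integrals of $e^{\beta V}$ use the trapezoid rule on the
  exponentiated integrand (the integrand is piecewise-smooth between
  depositions), accumulated with running log-sum-exp so that
  $\beta V > 700$ cannot overflow.
* Evaluation at a transition time uses the grid truncated there with the
  bias linearly interpolated at the endpoint — one quadrature rule shared
  by profiles, summaries, likelihood and generator, which is what makes the
  $\gamma = 1$ iMetaD identity hold to $10^{-12}$ relative and parameter
  recovery exact in distribution. (This is equivalent to linear
  interpolation of $\tau_{\text{accel}}$ up to $O(\Delta t^2)$.)
* Resampling to a common grid (ensemble-mean mode) interpolates linearly in
  $V$, not in $e^{\beta V}$.
* First-passage semantics everywhere: CV-threshold transitions are located
  by the first crossing with linear interpolation between frames, so grid
  resolution does not quantize transition times. COLVAR restart overlaps
  keep the last occurrence of each time.
* Degenerate inputs have defined behavior: all-censored ensembles refuse
  free-$k_0$ fits with an instructive error but accept fixed-$k_0$ ones;
  identical rescaled times give a rejected Poisson fit, not a crash;
  identical bootstrap inputs give zero-width intervals; an integrator step
  too large for the barrier raises a step-size error.
* Units are declarative only: energies are interpreted through the
  user-supplied $\beta$ (the analysis works in $\beta V$ throughout), and
  merging ensembles with clashing declared units is an error rather than a
  conversion.

## Design choices on open ground

* Whether historical EATR fits used per-trajectory or ensemble-averaged
  $f(t)$ is not determinable from the method descriptions alone; both are
  implemented, compared in tests, and selectable (`averaging=`), with the
  defaults chosen as described above.
* How non-transitioning runs were treated in published analyses is
  likewise unstated; here they are right-censored and always counted in
  the reports.
* The "treat this RC with caution" criterion (no inverse $\gamma$ vs
  $\bar\tau_{\text{accel}}$ relationship across iterations) has no
  published threshold; `iterationReport()` raises the flag when the
  $\gamma$–$\bar\tau_{\text{accel}}$ Spearman correlation is $\ge 0$ or
  when $\gamma$ is falling across iterations (a worsening series keeps the
  two quantities inversely related while still being pathological). Both
  pieces are documented conventions, not published thresholds.
* Best-RC selection is max $\hat\gamma$, with ties broken by smaller
  $\bar\tau_{\text{accel}}$, then earlier iteration; both quantities are
  printed so users can see when the two criteria disagree.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical claims are comfortably
resolved: hazard-inversion ensembles of 100–200 runs with 20 seeds
(resolving mean $\hat\gamma$ to about $\pm 0.01$), Langevin ladders of 16
runs per $\theta$ at an $8\,k_BT$ barrier, KS calibration with 100
repeats. Larger campaigns only sharpen the same comparisons.

## Known limitations

* $\gamma$ estimated against a misspecified $k_0$ is shifted; relative
  comparisons across RC iterations within one system are robust to this,
  absolute values are not.
* The Kramers reference rate at an $8\,k_BT$ barrier carries finite-barrier
  corrections of order 10–20 %, which propagate into the absolute
  $\hat\gamma$ of the toy-system analyses (their orderings are unaffected).
* The KS p-value with a fitted $\tau$ is conservative unless the bootstrap
  mode is used.
* With tens of runs and weak bias the likelihood in $\gamma$ is flat;
  expect wide bootstrap intervals and boundary hits, and prefer fixed-$k_0$
  fits there.
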