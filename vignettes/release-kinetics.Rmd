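---
title: "Classical and multifractal modelling of micellar drug release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical and multifractal modelling of micellar drug release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfrelease)
library(dplyr)
```

## The system and the data

pH-sensitive P2VP-b-PEO diblock copolymers self-assemble into micelles with
a glassy ("frozen-in") hydrophobic core that encapsulates a hydrophobic
drug. Below the P2VP pKa (~4.5) the core protonates and the micelles
disassemble, releasing their load quickly and almost completely; at
intestinal and physiological pH the micelles stay intact and release is
diffusion-controlled, slower and incomplete. The observable is a cumulative
release curve per sample and medium: time in hours against released drug as
a percentage of the encapsulated amount, typically followed for 200–300 h
with a plateau between roughly 47 and 95% depending on sample and pH.

`mfrelease` represents these data as plain long tibbles keyed by
`(sample_id, pH)` with columns `time_h` and `released_pct`, read and written
as comma-delimited text (`read_release_table()`, `write_release_table()`).
Raw curves need not be monotone; values just above 100% (assay overshoot up
to 110%) and positive release at `t = 0` (burst) are kept but flagged.

## Loading and encapsulation efficiencies

For a feed of `polymer_mass_mg` + `drug_added_mg` and a measured content of
`c` mg drug per g of recovered micelle powder,

$$DLE(\%) = \frac{m_{drug}}{m_{polymer}+m_{drug}}\times 100 = \frac{c}{10},
\qquad DEE(\%) = \frac{m_{drug}}{m_{added}}\times 100,$$

because the recovered powder is itself composed of polymer + drug. The two
are linked by the feed ratio: `DEE = DLE × (m_polymer + m_drug)/m_added`.
Report tables round half-up to 2 decimals (half-even rounding would
misprint a value ending in 5 at the third decimal, e.g. 70.345 → 70.34).
Calibration lines are forced through the origin, `a = Σxy/Σx²`, with R²
computed against the through-origin model, matching how spectrophotometric
curcumin calibrations are reported.

## The Ritger–Peppas layer

The empirical power law $M_t/M_\infty = k\,t^n$ is fitted by ordinary least
squares of $\ln(M_t/M_\infty)$ on $\ln t$; the slope is $n$ and
$e^{\mathrm{intercept}}$ is $k$. Choices worth stating:

* **Normalization.** `"plateau"` (default) uses the final observed release
  as $M_\infty$; `"total_load"` uses 100% of the encapsulated drug. The
  exponent is invariant under rescaling of the release axis, so the choice
  only affects $k$.
* **Window.** The full curve by default. The classical rule of fitting only
  the first 60% of release is available through the `window` argument but
  not imposed.
* **Exclusions.** Points with $t = 0$ or zero release cannot enter the log
  fit; they are dropped and counted, and at least 3 usable points are
  required. A fitted exponent outside (0, 1) warns rather than errors —
  it simply voids the usual mechanistic reading.
* `method = "nls"` refits $k t^n$ by Levenberg–Marquardt starting from the
  log–log estimates, for users who prefer untransformed residuals.

On noiseless power-law data the estimates are exact to ~1e-12; under 2%
multiplicative increment noise the exponent is recovered well within ±0.02
across the panel.

## The multifractal Fokker–Planck layer

In the multifractal (scale-relativity) picture the drug ensemble is
described by a states density ρ whose conservation law, once the
differentiable and non-differentiable velocity fields compensate
(`V_D = −V_F`) and the polymer network acts through a constant-field
potential vector, becomes a linear-drift Fokker–Planck equation

$$\partial_t\rho + \partial_x(-\eta x \rho) - D\,\partial_{xx}\rho = 0,
\qquad \eta = gB/2,$$

with $D = 2\lambda(dt)^{2/f(\alpha)-1}$ tying the diffusion-type
coefficient to the scale resolution $dt$ and singularity spectrum
$f(\alpha)$ (`scale_params()`, `lambda_from_D()`). Its solution is a
Gaussian with mean $x_0 e^{-\eta t}$ and variance
$(D/\eta)(1-e^{-2\eta t})$ (`ou_density()`, `ou_moments()`). Three
independent oracles verify this inside the package: adaptive quadrature
(unit mass and moments to 1e-8), centred finite differences (PDE residual
decaying at second order, ratio ≈ 4 per mesh halving), and a seeded
Euler–Maruyama ensemble of $dx = -\eta x\,d\tau + \sqrt{2D}\,dW$.

**Integrator step.** The stability bound `step < 1/(2η)` is enforced as an
error, but the default is much finer, `0.005/η`: Euler–Maruyama has O(step)
moment bias, and at 10⁵ particles the Monte-Carlo standard errors are small
enough that a step of `0.1/η` (or even `0.01/η` for the variance at short
times) would leave a visible bias. At `0.005/η` the bias sits well inside
the 3·SE band at every checked time.

**The release law.** The model's only time-dependent scale is the standard
deviation, so the cumulative release curve is identified with
$$M(t) = \sqrt{(D/\eta)\left(1-e^{-2\eta t}\right)},$$
with unit prefactor. This choice is deliberate and matters: its early-time
behaviour $\sqrt{2Dt}$ has log–log slope 1/2, consistent with the
Fickian-diffusion exponents found by the power-law layer, its plateau
$\sqrt{D/\eta}$ matches the observed saturation, and fixing the prefactor
at 1 removes the amplitude degeneracy so that $(D, \eta)$ are identifiable
from a curve's rate and plateau. Alternative mappings from the transition
density to a release curve (e.g. first-passage constructions with an
absorbing boundary) exist but are not implemented.

**Two-timescale fits and the fractalization degree.** Following the
two-scale reading of release dynamics, `fit_multifractal_release()` splits
a curve at a breakpoint (default 50 h, configurable) and fits the release
law independently on each side, with no continuity constraint. The fitted
`D` per segment is reported as that scale's *fractalization degree*: a low
degree means weakly broken geodesics (gentle early dynamics), a high degree
strongly fractalized, cumulative large-scale dynamics. The late degree
exceeding the early one is the expected signature. The numbers are in the
release units of the curve being fitted; no attempt is made to reconcile
them with any externally tabulated units.

**Fitting objective.** Each segment fit is Levenberg–Marquardt in
$(\log D, \log\eta)$ (positivity by construction) with a multi-start over
η on a log grid ($10^{-4}$–$10^0$, 9 points) and D initialised from
plateau²·η. The default objective is least squares on the **log increments**
between consecutive observations rather than on the cumulative levels.
Reason: each increment of a cumulative assay derives from an independent
reading, so increment errors are approximately independent while
cumulative-level errors are a correlated random walk; on the truncated late
window the (D, η) ridge amplifies correlated level noise (measured
estimator s.d. ≈ 2.8% at 2% noise, versus ≈ 1.0% for the increment
objective). Plain level-domain least squares remains available as
`objective = "levels"`. Segment R² is always reported on the levels.

## The geometry and pattern layers

The multifractal stress tensor leads to characteristic cubic equations, and
a cubic $a_0X^3+3a_1X^2+3a_2X+a_3$ with distinct roots is parameterized by
the roots $(h, \bar h)$ of its Hessian together with a unit-type parameter
$k$; the homographic action on roots induces a simply transitive action on
$(h,\bar h,k)$ whose generators close the sl(2,R) brackets
$[B_1,B_2]=B_1$, $[B_2,B_3]=B_3$, $[B_3,B_1]=-2B_2$. In the real chart
$h=u+iv$, $k=e^{i\theta}$ the invariant 1-forms give the extended metric
$-(d\theta+du/v)^2+(du^2+dv^2)/v^2$, which reduces to the Poincaré
upper-half-plane metric exactly when the angle-of-parallelism constraint
$d\theta=-du/v$ holds.

Numerical conventions:

* Roots are ordered by real part then imaginary part; $h$ is the Hessian
  root with positive imaginary part (so $v>0$); the cubic root of unity is
  $\varepsilon=(-1+i\sqrt3)/2$; $X_2$ and $X_3$ are labelled so their
  Möbius preimages are $\varepsilon k$ and $\varepsilon^2 k$ exactly.
* Cubic roots from `polyroot()` are polished by Newton steps, and the
  triple $(h,\bar h,k)$ is then refined by a complex Newton solve of the
  three reconstruction equations (the map is invertible), bringing the
  reconstruction residual to machine precision even for poorly conditioned
  cubics. Degeneracy (|discriminant| < 1e-12 × coefficient scale) errors.
* Bracket relations are verified with central differences on the generator
  coefficients — exact for polynomials of degree ≤ 2, so the defect is pure
  roundoff (< 1e-11).
* The fuzz suite (`geometry_selftest()`) draws root triples separated by at
  least 0.05 and keeps Möbius denominators above 0.2; near-pole transforms
  are excluded because they amplify roundoff without testing anything new.

Non-stationary dynamics are rendered by the harmonic-map solution
$$h = \frac{\cosh(\Phi/2)-\sinh(\Phi/2)e^{-i\alpha}}
           {\cosh(\Phi/2)+\sinh(\Phi/2)e^{-i\alpha}},$$
with $\alpha = 2\Omega t$ giving the pattern field $h(\Omega,t)$ on
dimensionless grids (default 512², Φ = 2.35; ranges 0–20 up to 0–800). The
modulus, real and imaginary parts are the global, differentiable and
non-differentiable resolution views. The field is pole-free (denominator
≥ 2 for Φ ≥ 0), periodic in t with period π/Ω, and depends on Ω and t only
through their product — hence the self-similar appearance across nested
ranges. The grid evaluator uses the expanded real-arithmetic form and is
cross-checked against the direct complex form at 1e-12.

**A sign convention worth knowing.** With α fixed and Φ harmonic in the
spatial coordinates, the solution traces a geodesic of the hyperbolic plane
through geodesic polar coordinates ($\tanh(\Phi/2)e^{-i\alpha}$ lies in the
unit disk), and the resulting field takes values in the *right* half-plane
($h(\alpha=0)=e^{-\Phi}>0$). The harmonic-map Euler equations
$(w-\bar w)\nabla^2 w = 2(\nabla w)^2$ are written for the *upper*
half-plane, so `euler_residual()` evaluates them on the quarter-rotated
field $w = ih$ — in that chart the residual is pure discretization error
and halving the mesh divides it by ≈ 4. The companion equation for
$\bar w$ is the complex conjugate of the first and is not evaluated
separately. A non-harmonic Φ is detected by a discrete-Laplacian check and
flagged.

## The synthetic generator

There is no public deposit of the raw curves, so the generator *defines*
the study conditions the tests assume:

* 3 samples × 3 pH media; per-curve plateaus (95.2 … 46.8%), durations
  (300/264/218 h) and exponent truths (0.41–0.57) matching the reported
  panel; sparse default grid of 25 points over 0–300 h, denser before 50 h,
  always observing the run endpoint.
* Noise: multiplicative Gaussian on release increments (default 2%
  relative), then re-accumulated — curves stay non-decreasing and the
  scatter scales with the local release step, as assay noise does.
* `two_regime` curves: late scale uses `eta_late = 0.008 /h` (so the
  plateau is ~99% approached by the 300 h end of the window) and the
  early scale's asymptote is placed at 30% of the overall plateau — about
  30% of the release mass precedes the 50 h breakpoint by construction.
  Degrees default to a 9-pair set spanning 1.1–10.4 with the late degree
  the larger in every row. These curves are in native release units, not
  rescaled to %, to preserve the prefactor-1 identifiability convention.
* Parameter-recovery experiments use a denser sampling (`recovery_times()`:
  hourly to 50 h, 2-hourly after) than the default panel; sparse grids are
  what routine assays produce, dense grids are what a recovery study needs.
* A single root seed drives everything; same seed, same panel, bit for bit.

What passing tests do **not** show about real data: the noise model is a
convention (true spectrophotometric error structure is unknown), curves are
exactly model-generated (no model misspecification), and pH enters only
through the configured plateaus/rates (no protonation chemistry or
demicellization thermodynamics is simulated).

## Problem sizes and runtime choices

The verification suite uses: 10⁵-particle ensembles at 5 snapshot times
(Kolmogorov–Smirnov at t = 1), finite-difference meshes up to 161 × 81
(Fokker–Planck) and 81² (harmonic maps), 1000-cubic geometry fuzzing, and
512² pattern grids for the four published ranges. These sizes hold every
tolerance with comfortable margin while keeping the whole suite under a
minute of compute on a single core.

## Known limitations

* The mapping from transition density to cumulative release is a modelling
  choice (σ-growth with unit prefactor); fractalization degrees therefore
  carry the units of the fitted curve and are not comparable across
  different normalizations.
* Independent segment fits mean the fitted curves need not join at the
  breakpoint; that mirrors the two-scale reading but forfeits continuity
  information.
* The Schrödinger-type formulation of the same dynamics is documented as
  equivalent but not implemented as a solver, and the multifractal stress
  tensor itself is not computed — only its cubic/geometric consequences.
* Pattern fields are qualitative surfaces (channels, pairing,
  self-similarity); no formula links `h(Ω,t)` to measurable release mass,
  and none is asserted.
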