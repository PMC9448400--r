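# mfrelease

Kinetic modelling of cumulative drug release from pH-sensitive block-copolymer
nanomicelles, for formulation scientists and modellers who want both the
classical empirical analysis and a multifractal (scale-relativity-flavoured)
stochastic description of the same curves.

The package covers four layers of analysis:

1. **Loading and encapsulation efficiency.** From the feed masses and the
   measured drug content of the recovered micelle powder,
   `DLE(%) = m_drug-in-micelles / (m_polymer + m_drug) × 100` and
   `DEE(%) = m_drug-in-micelles / m_drug-added × 100`, plus through-origin
   spectrophotometric calibration lines (`y = a·x`).

2. **Ritger–Peppas power law.** `Mt/M∞ = k·tⁿ`, fitted by log–log least
   squares (or direct nonlinear least squares); `n ≈ 0.5` signals Fickian
   diffusion. Works per curve or across a whole samples × pH panel.

3. **Multifractal Fokker–Planck release model.** The density-conservation
   law of the multifractal hydrodynamics reduces, under velocity-field
   compensation, to `∂tρ + ∂x(−ηxρ) − D∂xxρ = 0` whose solution is a
   Gaussian with mean `x0·e^{−ηt}` and variance `(D/η)(1 − e^{−2ηt})`.
   The implied release law `M(t) = √((D/η)(1 − e^{−2ηt}))` has early-time
   exponent 1/2 and a plateau `√(D/η)`. Fitting it independently below and
   above a 50 h breakpoint yields a per-timescale **fractalization degree**
   (the fitted `D`). A seeded Euler–Maruyama particle ensemble and
   finite-difference PDE residuals serve as built-in verification oracles.

4. **SL(2,R) geometry and harmonic patterns.** Cubics parameterized by their
   Hessian roots `(h, h̄, k)`, the homographic synchronization group and its
   sl(2,R) generators, the extended hyperbolic metric reducing to the
   Poincaré half-plane form under the angle-of-parallelism constraint, and
   the harmonic-map pattern fields `h(Ω, t)` (with `α = 2Ωt`, `Φ = 2.35`)
   whose modulus / real / imaginary parts are the global, differentiable and
   non-differentiable resolution views.

Because raw release measurements for this system are not publicly deposited,
the package ships a first-class synthetic generator (`generate_panel()`)
producing 3 samples × 3 pH panels with the plateau levels, durations,
exponents and two-regime structure the analysis assumes — every fitter is
exercised end-to-end against known truth.

## Worked example

```r
library(mfrelease)
library(dplyr)

# loading efficiencies of the three reference formulations
report_loading(generate_formulations())
#>   sample_id polymer_mass_mg drug_added_mg drug_in_micelles... dle_pct dee_pct
#> 1 A                     250            25                65.3    6.53   71.83
#> 2 B                     250            25                64.0    6.40   70.35
#> 3 C                     250            25                51.3    5.13   56.39

# a seeded synthetic panel with 2% noise, fitted with the power law
panel <- generate_panel(panel_config(generator = "ritger_peppas",
                                     noise_rel = 0.02, seed = 1))
report_ritger_peppas(panel)
#>      pH sample_id ef_pct duration_h      k     n r_squared n_points
#> 1   2   A           95.7        300 0.0438 0.549         1       24
#> 2   2   B           94.4        300 0.0784 0.446         1       24
#> ...                                        (n sits around 0.5 throughout)

# two-timescale fractal fit of a two-regime curve (truth: D = 5.2 / 10.4)
two <- generate_panel(panel_config(generator = "two_regime", noise_rel = 0.02,
                                   times = recovery_times(), seed = 1))
fit <- fit_multifractal_release(filter(two, sample_id == "A", pH == 2))
fit
#> Two-scale fractal fit (breakpoint 50 h, increments objective)
#>   fractalization degree: early 5.22, late 10.5; early mass fraction 0.30
glance(fit)
autoplot(fit)

# harmonic-map pattern field at the documented parameter
f <- harmonic_field(phi = 2.35, omega_range = c(0, 20), t_range = c(0, 20))
autoplot(f, "imaginary")
```

The loading report reproduces the reference efficiencies exactly; the fitted
exponents recover the generator truths (here to within 0.006); the fractal
fit recovers the early/late degrees 5.2 and 10.4 to within a few percent and
reports that ~30% of the release mass precedes the 50 h breakpoint.

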