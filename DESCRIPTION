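Package: mfrelease
Title: Classical and Multifractal Kinetic Modelling of Drug Release from
    Polymeric Nanomicelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cumulative drug-release curves from
    pH-sensitive block-copolymer nanomicelles. Implements drug loading and
    encapsulation efficiency calculations with through-origin calibration
    lines, Ritger-Peppas power-law fitting in log-log or direct nonlinear
    form, an Ornstein-Uhlenbeck-type Fokker-Planck release model with
    closed-form Gaussian transition density, hydrodynamic diagnostics and a
    seeded particle-ensemble simulation oracle, two-timescale segmented
    fits yielding per-scale fractalization degrees, the SL(2,R) homographic
    machinery linking cubic Hessian roots to the Poincare half-plane metric,
    and harmonic-map pattern fields over dimensionless frequency-time grids.
    A synthetic release-curve generator with controlled noise provides
    end-to-end testable panels emulating three copolymer samples in three
    pH media.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
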