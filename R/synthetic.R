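#' Default panel conditions for the synthetic generator
#'
#' The default panel emulates the study design the analysis assumes: three
#' copolymer samples (A, B, C with decreasing loading efficiency) released
#' in three pH media (2, 6.8, 7.4), observed over up to 300 h on a grid that
#' is denser before the 50 h breakpoint, with plateau levels, durations and
#' release exponents matching the reported per-curve values (plateaus
#' 95.2/94.3/94.1% at pH 2, 63.0/58.2/46.8% at pH 6.8, 80.8/61.6/58.8% at
#' pH 7.4; exponents 0.41-0.57). At pH 2 the micelles demicellize (core
#' protonation below the P2VP pKa of ~4.5), giving near-complete, fast
#' release; at higher pH the frozen-in micelles release by diffusion.
#'
#' @return A tibble with one row per (sample, pH): `sample_id`, `pH`,
#'   `plateau_pct`, `duration_h`, `n_true` (release exponent).
#' @export
default_panel_rows <- function() {
  tibble(
    pH = rep(c(2, 6.8, 7.4), each = 3),
    sample_id = rep(c("A", "B", "C"), 3),
    plateau_pct = c(95.2, 94.3, 94.1, 63.0, 58.2, 46.8, 80.8, 61.6, 58.8),
    duration_h = c(300, 300, 300, 264, 264, 264, 218, 264, 218),
    n_true = c(0.548, 0.445, 0.527, 0.417, 0.428, 0.519, 0.544, 0.410, 0.566)
  )
}

#' Configuration for the synthetic release-curve generator
#'
#' @param rows Per-curve conditions: a tibble like [default_panel_rows()].
#'   For `generator = "two_regime"` it must also carry `D_early` and
#'   `D_late` columns (fractalization-degree truths, release units); a
#'   default spanning 1.1-10.4 with `D_late >= D_early` in every row is
#'   supplied.
#' @param generator `"ritger_peppas"` (power-law curves with the row's
#'   exponent), `"ou_release"` (single-regime saturating curves from
#'   [release_from_ou()]) or `"two_regime"` (distinct early/late diffusion
#'   coefficients, breakpoint at 50 h, ~30% of the release mass before the
#'   breakpoint).
#' @param noise_rel Relative s.d. of the multiplicative Gaussian noise
#'   applied to release increments (default 0.02; increments stay
#'   non-negative, so curves stay non-decreasing).
#' @param times Sampling grid in hours. Default: 25 points over 0-300,
#'   denser before 50 h. Curves are truncated at each row's `duration_h`.
#' @param eta Relaxation rate (1/h) for `"ou_release"` (default 0.008: the
#'   plateau is ~99% reached by 300 h).
#' @param eta_late Late-scale relaxation rate for `"two_regime"` (default
#'   0.008, same reading of the 300 h window).
#' @param early_fraction Asymptotic early-scale release level as a fraction
#'   of the overall plateau for `"two_regime"` (default 0.3).
#' @param seed Integer seed; mandatory, threaded through all randomness.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(rows = default_panel_rows(),
                         generator = c("ritger_peppas", "ou_release", "two_regime"),
                         noise_rel = 0.02,
                         times = default_times(),
                         eta = 0.008, eta_late = 0.008,
                         early_fraction = 0.3,
                         seed) {
  generator <- match.arg(generator)
  if (missing(seed)) abort("seed is mandatory in panel_config()")
  rows <- as_tibble(rows)
  if (generator == "two_regime" && !all(c("D_early", "D_late") %in% names(rows))) {
    rows <- dplyr::left_join(rows, default_degrees(), by = c("pH", "sample_id"))
  }
  if (any(rows$plateau_pct <= 0 | rows$plateau_pct > 100)) {
    abort("plateau_pct must lie in (0, 100]")
  }
  if (noise_rel < 0) abort("noise_rel must be >= 0")
  if (length(times) == 0) abort("empty time grid")
  structure(list(rows = rows, generator = generator, noise_rel = noise_rel,
                 times = sort(unique(times)), eta = eta, eta_late = eta_late,
                 early_fraction = early_fraction, seed = as.integer(seed)),
            class = "panel_config")
}

#' @rdname panel_config
#' @export
default_times <- function() {
  c(0, 1, 2, 3, 5, 8, 12, 16, 22, 28, 36, 44, 50,
    60, 75, 90, 110, 130, 155, 180, 205, 230, 255, 280, 300)
}

#' @rdname panel_config
#' @export
default_degrees <- function() {
  tibble(
    pH = rep(c(2, 6.8, 7.4), each = 3),
    sample_id = rep(c("A", "B", "C"), 3),
    D_early = c(5.2, 2.4, 1.3, 3.1, 2.3, 1.4, 5.1, 2.04, 1.1),
    D_late = c(10.4, 10, 9, 3.8, 4.8, 6.2, 8.6, 4.53, 6.5)
  )
}

#' Generate a synthetic release-curve panel
#'
#' Produces one cumulative release curve per row of the configuration.
#' Noiseless curves follow the configured generator law exactly; noise is
#' applied multiplicatively to the release increments and re-accumulated, so
#' curves remain non-decreasing. Same seed, same curves; the generator truth
#' is attached as attribute `"truth"`.
#'
#' Generator laws (t in hours):
#' * `ritger_peppas`: `plateau * (t / duration)^n` — the power law with the
#'   row's exponent, normalized to reach the plateau at the end of the run.
#' * `ou_release`: `release_from_ou()` with `D = eta * plateau^2`, so the
#'   asymptotic plateau equals the row's plateau.
#' * `two_regime`: early scale (t <= 50) follows the release law with
#'   `D_early` and a relaxation rate placing its asymptote at
#'   `early_fraction` of the overall plateau; the late scale (t > 50)
#'   follows the law with `D_late` and `eta_late`. Amplitudes are in the
#'   model's native release units (the prefactor-1 convention that makes the
#'   fractalization degree identifiable), not rescaled to %.
#'
#' @param cfg A [panel_config()].
#' @return A [as_release_curves()] tibble with attribute `"truth"` (tibble
#'   of the per-curve generator parameters).
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  set.seed(cfg$seed)
  curves <- vector("list", nrow(cfg$rows))
  truths <- vector("list", nrow(cfg$rows))
  for (i in seq_len(nrow(cfg$rows))) {
    row <- cfg$rows[i, ]
    # truncate the grid at the run duration and observe the endpoint itself
    t <- sort(unique(c(cfg$times[cfg$times <= row$duration_h], row$duration_h)))
    clean <- switch(cfg$generator,
      ritger_peppas = {
        truths[[i]] <- tibble(pH = row$pH, sample_id = row$sample_id,
                              k_true = row$duration_h^(-row$n_true),
                              n_true = row$n_true,
                              plateau_pct = row$plateau_pct)
        row$plateau_pct * (t / row$duration_h)^row$n_true
      },
      ou_release = {
        D <- cfg$eta * row$plateau_pct^2
        truths[[i]] <- tibble(pH = row$pH, sample_id = row$sample_id,
                              D_true = D, eta_true = cfg$eta,
                              plateau_pct = row$plateau_pct)
        p <- ou_params(D = D, eta = cfg$eta)
        release_from_ou(t, p)
      },
      two_regime = {
        P <- sqrt(row$D_late / cfg$eta_late)   # overall asymptotic plateau
        eta_early <- row$D_early / (cfg$early_fraction * P)^2
        truths[[i]] <- tibble(pH = row$pH, sample_id = row$sample_id,
                              D_early = row$D_early, D_late = row$D_late,
                              eta_early = eta_early, eta_late = cfg$eta_late)
        pe <- ou_params(D = row$D_early, eta = eta_early)
        pl <- ou_params(D = row$D_late, eta = cfg$eta_late)
        ifelse(t <= 50, release_from_ou(t, pe), release_from_ou(t, pl))
      }
    )
    inc <- diff(c(0, clean))
    if (cfg$noise_rel > 0) {
      inc <- pmax(inc, 0) * (1 + rnorm(length(inc), 0, cfg$noise_rel))
      inc <- pmax(inc, 0)
    }
    released <- cumsum(inc)
    curves[[i]] <- tibble(sample_id = row$sample_id, pH = row$pH,
                          time_h = t, released_pct = pmin(released, 110))
  }
  out <- as_release_curves(dplyr::bind_rows(curves))
  attr(out, "truth") <- dplyr::bind_rows(truths)
  out
}

#' Reference and randomized drug-loading formulations
#'
#' Returns the three reference formulations of the study design (250 mg
#' copolymer + 25 mg drug, micelle drug contents 65.30 / 63.95 / 51.26
#' mg/g for samples A / B / C), optionally followed by randomized variants
#' for fuzzing the efficiency algebra.
#'
#' @param n_random Number of randomized variants to append (default 0).
#' @param seed Seed used when `n_random > 0`.
#' @return A formulations tibble accepted by [compute_dle_dee()].
#' @export
generate_formulations <- function(n_random = 0, seed = 1) {
  base <- tibble(
    sample_id = c("A", "B", "C"),
    polymer_mass_mg = 250, drug_added_mg = 25,
    drug_in_micelles_mg_per_g = c(65.30, 63.95, 51.26)
  )
  if (n_random > 0) {
    set.seed(seed)
    extra <- tibble(
      sample_id = paste0("R", seq_len(n_random)),
      polymer_mass_mg = runif(n_random, 50, 500),
      drug_added_mg = runif(n_random, 5, 100),
      drug_in_micelles_mg_per_g = runif(n_random, 0, 200)
    )
    base <- dplyr::bind_rows(base, extra)
  }
  base
}

#' Dense sampling grid for recovery experiments
#'
#' Hourly sampling to the 50 h breakpoint and 2-hourly after, the
#' spectrophotometric sampling density used by the parameter-recovery
#' studies (the default panel grid of [default_times()] is the sparser
#' 25-point schedule).
#'
#' @param t_end End of the run (hours).
#' @return Numeric vector of times.
#' @export
recovery_times <- function(t_end = 300) {
  c(seq(1, 50, by = 1), seq(52, t_end, by = 2))
}
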