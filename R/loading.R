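#' Drug loading and encapsulation efficiencies
#'
#' For micelles prepared from `polymer_mass_mg` of copolymer and
#' `drug_added_mg` of drug, with a measured drug content of
#' `drug_in_micelles_mg_per_g` (mg of drug per gram of recovered micelle
#' powder), the loading efficiency is the drug mass over the total
#' polymer + drug mass and the encapsulation efficiency is the encapsulated
#' drug over the drug fed:
#' \deqn{DLE(\%) = \frac{m_{drug\,in\,micelles}}{m_{polymer} + m_{drug}} \times 100,
#'   \qquad DEE(\%) = \frac{m_{drug\,in\,micelles}}{m_{drug\,added}} \times 100.}
#' Since the recovered micelle powder is composed of polymer + drug, a content
#' of c mg/g translates directly to \eqn{DLE = c/10} %.
#'
#' @param formulations Data frame with numeric columns `polymer_mass_mg`
#'   (> 0), `drug_added_mg` (>= 0) and `drug_in_micelles_mg_per_g`
#'   (in `[0, 1000]`). Other columns (e.g. `sample_id`) pass through.
#' @return The input as a tibble with `dle_pct` and `dee_pct` columns
#'   appended (unrounded; report helpers round to 2 decimals).
#' @examples
#' compute_dle_dee(tibble::tibble(
#'   sample_id = "A", polymer_mass_mg = 250, drug_added_mg = 25,
#'   drug_in_micelles_mg_per_g = 65.30
#' ))
#' @export
compute_dle_dee <- function(formulations) {
  f <- as_tibble(formulations)
  needed <- c("polymer_mass_mg", "drug_added_mg", "drug_in_micelles_mg_per_g")
  missing_cols <- setdiff(needed, names(f))
  if (length(missing_cols) > 0) {
    abort(paste0("formulations table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(f$polymer_mass_mg <= 0)) abort("polymer_mass_mg must be > 0")
  if (any(f$drug_added_mg < 0)) abort("drug_added_mg must be >= 0")
  if (any(f$drug_in_micelles_mg_per_g < 0 | f$drug_in_micelles_mg_per_g > 1000)) {
    abort("drug_in_micelles_mg_per_g must lie in [0, 1000]")
  }
  if (any(f$drug_added_mg == 0 & f$drug_in_micelles_mg_per_g > 0)) {
    abort("DEE undefined: no drug added but nonzero drug content measured",
          class = "mfrelease_undefined_efficiency")
  }
  f$dle_pct <- f$drug_in_micelles_mg_per_g / 10
  feed_frac_pct <- 100 * f$drug_added_mg / (f$polymer_mass_mg + f$drug_added_mg)
  f$dee_pct <- ifelse(f$drug_added_mg == 0, 0, f$dle_pct / feed_frac_pct * 100)
  f
}

#' Fit a through-origin spectrophotometric calibration line
#'
#' Least-squares fit of `absorbance = slope * concentration` with no
#' intercept (the calibration convention for drug quantification in DMSO);
#' the slope is \eqn{\sum x y / \sum x^2} and \eqn{R^2} is computed against
#' the through-origin model.
#'
#' @param data Data frame holding the calibration points.
#' @param concentration,absorbance Column names (tidy-eval) of the
#'   concentration (ug/ml) and absorbance variables.
#' @return An object of class `calibration_line` with fields `slope`,
#'   `r_squared`, `n` and the data used. Has [tidy()] and [glance()] methods.
#' @examples
#' d <- tibble::tibble(conc = c(5, 10, 20, 40), abs = 0.0178 * c(5, 10, 20, 40))
#' fit_calibration(d, conc, abs)
#' @export
fit_calibration <- function(data, concentration, absorbance) {
  x <- dplyr::pull(data, {{ concentration }})
  y <- dplyr::pull(data, {{ absorbance }})
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("need at least 2 calibration points")
  if (all(x == 0)) {
    abort("degenerate calibration design: all concentrations are zero",
          class = "mfrelease_degenerate_design")
  }
  slope <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)  # through-origin total sum of squares
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = slope, r_squared = r2, n = length(x),
         data = tibble(concentration = x, absorbance = y)),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Through-origin calibration line: y = %.4g x  (R^2 = %.4f, n = %d)\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_line`.
#' @param ... Unused.
#' @method tidy calibration_line
#' @export
tidy.calibration_line <- function(x, ...) {
  tibble(term = "slope", estimate = x$slope)
}

#' @rdname fit_calibration
#' @method glance calibration_line
#' @export
glance.calibration_line <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n)
}

#' Convert an absorbance reading to a concentration
#'
#' @param absorbance Absorbance value(s).
#' @param line A `calibration_line` from [fit_calibration()], or a positive
#'   numeric slope.
#' @return Concentration(s) in ug/ml: `absorbance / slope`.
#' @export
absorbance_to_concentration <- function(absorbance, line) {
  slope <- if (inherits(line, "calibration_line")) line$slope else line
  if (!is.numeric(slope) || length(slope) != 1 || slope <= 0) {
    abort("calibration slope must be a single positive number")
  }
  absorbance / slope
}
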