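#' Two-timescale fractal fit of a release curve
#'
#' Splits a cumulative release curve at a temporal breakpoint (default 50 h)
#' and fits the release law of [release_from_ou()],
#' \eqn{M(t) = \sqrt{(D/\eta)(1-e^{-2\eta t})}}, independently to the early
#' (`t <= breakpoint`) and late (`t > breakpoint`) segments with no
#' continuity constraint. The fitted diffusion-type coefficient `D` of each
#' segment is reported as that scale's fractalization degree.
#'
#' Each segment fit is Levenberg-Marquardt least squares in `(log D,
#' log eta)` with a multi-start over `eta` on a log grid and `D` initialized
#' from plateau^2 * eta. The default objective minimizes residuals of the
#' LOG INCREMENTS between consecutive observations, which is the
#' generalized-least-squares objective matched to multiplicative noise on
#' release increments (each increment derives from an independent
#' spectrophotometric reading, so increment errors are independent while
#' cumulative-level errors are a correlated random walk). Set
#' `objective = "levels"` for plain least squares on the cumulative values.
#'
#' @param curve A single release curve (see [as_release_curves()]).
#' @param breakpoint_h Breakpoint between the two temporal scales, hours.
#' @param objective `"increments"` (default) or `"levels"`.
#' @param eta_grid Multi-start grid for the relaxation rate (1/h).
#' @return An object of class `fractal_fit`: `segments` tibble (one row per
#'   segment: `segment`, `t_min`, `t_max`, `n_points`, `D`, `eta`,
#'   `r_squared`), `fractalization_degree_early`,
#'   `fractalization_degree_late`, `early_mass_fraction` (release at the
#'   breakpoint over release at the end, linearly interpolated) and
#'   `breakpoint_h`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_multifractal_release <- function(curve, breakpoint_h = 50,
                                     objective = c("increments", "levels"),
                                     eta_grid = 10^seq(-4, 0, length.out = 9)) {
  objective <- match.arg(objective)
  curve <- as_release_curves(curve)
  if (nrow(dplyr::distinct(curve, .data$sample_id, .data$pH)) > 1) {
    abort("fit_multifractal_release expects a single curve; see fit_fractal_panel()")
  }
  t <- curve$time_h
  y <- curve$released_pct
  keep <- t > 0
  t <- t[keep]; y <- y[keep]
  early <- t <= breakpoint_h
  if (sum(early) < 3 || sum(!early) < 3) {
    abort(sprintf("need >= 3 points on each side of the %g h breakpoint (have %d / %d)",
                  breakpoint_h, sum(early), sum(!early)))
  }
  seg_fit <- function(ts, ys, from_origin) {
    fit_ou_segment(ts, ys, objective = objective, eta_grid = eta_grid,
                   from_origin = from_origin)
  }
  fe <- seg_fit(t[early], y[early], from_origin = TRUE)
  fl <- seg_fit(t[!early], y[!early], from_origin = FALSE)
  segments <- tibble(
    segment = c("early", "late"),
    t_min = c(min(t[early]), min(t[!early])),
    t_max = c(max(t[early]), max(t[!early])),
    n_points = c(sum(early), sum(!early)),
    D = c(fe$D, fl$D), eta = c(fe$eta, fl$eta),
    r_squared = c(fe$r_squared, fl$r_squared)
  )
  y_bp <- approx(t, y, xout = min(breakpoint_h, max(t)), rule = 2)$y
  structure(
    list(segments = segments,
         fractalization_degree_early = fe$D,
         fractalization_degree_late = fl$D,
         early_mass_fraction = y_bp / y[which.max(t)],
         breakpoint_h = breakpoint_h, objective = objective,
         sample_id = curve$sample_id[1], pH = curve$pH[1],
         data = tibble(time_h = t, released = y)),
    class = "fractal_fit"
  )
}

# Fit M(t) = sqrt((D/eta)(1 - exp(-2 eta t))) to one segment.
# from_origin: anchor the first increment at (0, 0); otherwise increments are
# taken within the segment only (the cross-breakpoint increment is dropped,
# since the two scales are fitted as separate laws).
fit_ou_segment <- function(t, y, objective, eta_grid, from_origin) {
  stopifnot(length(t) >= 3)
  model_sigma <- function(t, lD, le) {
    sqrt((exp(lD) / exp(le)) * (1 - exp(-2 * exp(le) * t)))
  }
  if (objective == "increments") {
    if (from_origin) {
      ti <- t; tp <- c(0, head(t, -1)); inc <- y - c(0, head(y, -1))
    } else {
      ti <- t[-1]; tp <- head(t, -1); inc <- diff(y)
    }
    ok <- inc > 0
    if (sum(ok) < 3) {
      abort("fewer than 3 positive increments in segment",
            class = "mfrelease_fit_failure")
    }
    inc_dat <- data.frame(t = ti[ok], tp = tp[ok], li = log(inc[ok]))
  }
  best <- NULL; best_rss <- Inf
  t_max <- max(t); y_max <- max(y)
  for (eta0 in eta_grid) {
    D0 <- eta0 * y_max^2 / max(1e-12, 1 - exp(-2 * eta0 * t_max))
    start <- list(lD = log(D0), le = log(eta0))
    f <- tryCatch({
      if (objective == "levels") {
        minpack.lm::nlsLM(y ~ model_sigma(t, lD, le),
                          data = data.frame(t = t, y = y), start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          li ~ log(model_sigma(t, lD, le) - model_sigma(tp, lD, le)),
          data = inc_dat, start = start,
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(residuals(f)^2)
    if (is.finite(rss) && rss < best_rss) { best_rss <- rss; best <- f }
  }
  if (is.null(best)) {
    abort("segment fit failed to converge from any start on the eta grid",
          class = "mfrelease_fit_failure")
  }
  D_hat <- exp(unname(coef(best)["lD"]))
  eta_hat <- exp(unname(coef(best)["le"]))
  pred <- model_sigma(t, log(D_hat), log(eta_hat))
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  list(D = D_hat, eta = eta_hat, r_squared = r2)
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("Two-scale fractal fit (breakpoint %g h, %s objective)\n",
              x$breakpoint_h, x$objective))
  cat(sprintf("  fractalization degree: early %.3g, late %.3g; early mass fraction %.2f\n",
              x$fractalization_degree_early, x$fractalization_degree_late,
              x$early_mass_fraction))
  print(x$segments)
  invisible(x)
}

#' @rdname fit_multifractal_release
#' @param x A `fractal_fit` object.
#' @param ... Unused.
#' @method tidy fractal_fit
#' @export
tidy.fractal_fit <- function(x, ...) {
  tidyr::pivot_longer(x$segments[c("segment", "D", "eta")],
                      cols = c("D", "eta"),
                      names_to = "term", values_to = "estimate")
}

#' @rdname fit_multifractal_release
#' @method glance fractal_fit
#' @export
glance.fractal_fit <- function(x, ...) {
  tibble(degree_early = x$fractalization_degree_early,
         degree_late = x$fractalization_degree_late,
         early_mass_fraction = x$early_mass_fraction,
         breakpoint_h = x$breakpoint_h,
         r_squared_early = x$segments$r_squared[1],
         r_squared_late = x$segments$r_squared[2])
}

#' @rdname fit_multifractal_release
#' @param object A `fractal_fit` object.
#' @method autoplot fractal_fit
#' @export
autoplot.fractal_fit <- function(object, ...) {
  d <- object$data
  seg <- object$segments
  curves <- purrr::pmap(seg, function(segment, t_min, t_max, n_points, D, eta,
                                      r_squared) {
    tt <- seq(t_min, t_max, length.out = 100)
    tibble(segment = segment, time_h = tt,
           released = sqrt((D / eta) * (1 - exp(-2 * eta * tt))))
  })
  curves <- dplyr::bind_rows(curves)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$released)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$segment)) +
    ggplot2::geom_vline(xintercept = object$breakpoint_h, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "time (h)", y = "cumulative release",
                  title = sprintf("fractalization degree: early %.3g / late %.3g",
                                  object$fractalization_degree_early,
                                  object$fractalization_degree_late)) +
    ggplot2::theme_minimal()
}

#' Two-timescale fractal fit of every curve of a panel
#'
#' @inheritParams fit_multifractal_release
#' @param curves A release-curve table.
#' @return A tibble with one row per `(sample_id, pH)` curve: the two
#'   fractalization degrees, relaxation rates, fit quality per segment and
#'   the early mass fraction.
#' @export
fit_fractal_panel <- function(curves, breakpoint_h = 50,
                              objective = c("increments", "levels")) {
  objective <- match.arg(objective)
  pieces <- split_curves(curves)
  rows <- purrr::map(pieces, function(cv) {
    fit <- fit_multifractal_release(cv, breakpoint_h = breakpoint_h,
                                    objective = objective)
    tibble(pH = cv$pH[1], sample_id = cv$sample_id[1],
           degree_early = fit$fractalization_degree_early,
           degree_late = fit$fractalization_degree_late,
           eta_early = fit$segments$eta[1], eta_late = fit$segments$eta[2],
           r_squared_early = fit$segments$r_squared[1],
           r_squared_late = fit$segments$r_squared[2],
           early_mass_fraction = fit$early_mass_fraction)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$pH, .data$sample_id)
}
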