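#' Ritger-Peppas power-law release prediction
#'
#' Evaluates the empirical power law \eqn{M_t/M_\infty = k t^n} for
#' fractional drug release. Values are capped at 1 (complete release) with a
#' warning; the uncapped values are retained in the `"uncapped"` attribute
#' when capping occurs.
#'
#' @param k Release rate constant (h^-n), > 0.
#' @param n Release exponent (dimensionless), > 0. `n ~ 0.5` indicates
#'   Fickian diffusion.
#' @param t Time(s) in hours, >= 0.
#' @return Released fraction(s) in `[0, 1]`.
#' @examples
#' rp_predict(0.1, 0.5, 4)   # 0.2
#' @export
rp_predict <- function(k, n, t) {
  if (!is.numeric(k) || any(k <= 0)) abort("k must be > 0")
  if (!is.numeric(n) || any(n <= 0)) abort("n must be > 0")
  if (any(t < 0)) abort("t must be >= 0")
  frac <- k * t^n
  if (any(frac > 1)) {
    warn("predicted release fraction exceeds 1; capped at complete release")
    out <- pmin(frac, 1)
    attr(out, "uncapped") <- frac
    return(out)
  }
  frac
}

#' Fit the Ritger-Peppas model to a release curve
#'
#' Default fit is ordinary least squares of \eqn{\ln(M_t/M_\infty)} on
#' \eqn{\ln t} (the linearized form matching standard release-kinetics
#' practice): the slope is `n`, `exp(intercept)` is `k`, and \eqn{R^2} comes
#' from the log-log regression. Points with `t = 0` or zero release cannot
#' enter the log fit; they are excluded and counted. `method = "nls"` fits
#' \eqn{k t^n} directly by Levenberg-Marquardt nonlinear least squares
#' instead, seeded from the log-log estimates.
#'
#' Normalization `"plateau"` divides by the final observed release
#' (\eqn{M_\infty} = last value of the curve), `"total_load"` by 100%
#' of the encapsulated drug.
#'
#' @param curve A single release curve (one `(sample_id, pH)` key) as
#'   accepted by [as_release_curves()].
#' @param window Optional `c(t_min, t_max)` in hours restricting the fit
#'   (e.g. `c(0, t60)` for the classical "first 60%" rule); default the full
#'   curve.
#' @param normalization `"plateau"` (default) or `"total_load"`.
#' @param method `"loglog"` (default) or `"nls"`.
#' @return An object of class `rp_fit` with fields `k`, `n`, `r_squared`,
#'   `window`, `normalization`, `n_points`, `n_excluded` and the fitted data;
#'   has [tidy()], [glance()] and [autoplot()] methods. A release exponent
#'   outside (0, 1) triggers a warning, not an error.
#' @export
fit_ritger_peppas <- function(curve, window = NULL,
                              normalization = c("plateau", "total_load"),
                              method = c("loglog", "nls")) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  curve <- as_release_curves(curve)
  if (nrow(dplyr::distinct(curve, .data$sample_id, .data$pH)) > 1) {
    abort("fit_ritger_peppas expects a single curve; see fit_rp_panel()")
  }
  t <- curve$time_h
  y <- curve$released_pct
  if (length(unique(t)) < 2) abort("all time points equal; cannot fit")
  m_inf <- if (normalization == "plateau") y[which.max(t)] else 100
  if (m_inf <= 0) abort("non-positive normalization constant")
  frac <- y / m_inf

  in_window <- rep(TRUE, length(t))
  if (!is.null(window)) in_window <- t >= window[1] & t <= window[2]
  usable <- in_window & t > 0 & frac > 0
  n_excluded <- sum(in_window) - sum(usable)
  if (sum(usable) < 3) {
    abort("fewer than 3 usable points (t > 0, release > 0) in the window")
  }
  lt <- log(t[usable]); lf <- log(frac[usable])
  if (sd(lf) == 0) {
    # constant release: zero slope, k = the constant level
    n_hat <- 0; k_hat <- exp(lf[1]); r2 <- 1
  } else {
    ols <- lm(lf ~ lt)
    n_hat <- unname(coef(ols)[2])
    k_hat <- unname(exp(coef(ols)[1]))
    r2 <- summary(ols)$r.squared
  }
  if (method == "nls") {
    dat <- data.frame(t = t[usable], f = frac[usable])
    nfit <- minpack.lm::nlsLM(f ~ exp(lk) * t^n, data = dat,
                              start = list(lk = log(k_hat), n = max(n_hat, 1e-3)),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    k_hat <- exp(unname(coef(nfit)["lk"]))
    n_hat <- unname(coef(nfit)["n"])
    ss_res <- sum(residuals(nfit)^2)
    ss_tot <- sum((dat$f - mean(dat$f))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  }
  if (n_hat <= 0 || n_hat >= 1) {
    warn(sprintf("release exponent n = %.3f outside (0, 1); mechanism interpretation unreliable", n_hat))
  }
  structure(
    list(k = k_hat, n = n_hat, r_squared = max(0, min(1, r2)),
         window = c(min(t[usable]), max(t[usable])),
         normalization = normalization, method = method,
         m_inf = m_inf, n_points = sum(usable), n_excluded = n_excluded,
         sample_id = curve$sample_id[1], pH = curve$pH[1],
         data = tibble(time_h = t[usable], fraction = frac[usable])),
    class = "rp_fit"
  )
}

#' @export
print.rp_fit <- function(x, ...) {
  cat(sprintf("Ritger-Peppas fit (%s, %s): k = %.4g h^-n, n = %.3f, R^2 = %.4f (%d points)\n",
              x$method, x$normalization, x$k, x$n, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_ritger_peppas
#' @param x An `rp_fit` object.
#' @param ... Unused.
#' @method tidy rp_fit
#' @export
tidy.rp_fit <- function(x, ...) {
  tibble(term = c("k", "n"), estimate = c(x$k, x$n))
}

#' @rdname fit_ritger_peppas
#' @method glance rp_fit
#' @export
glance.rp_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points,
         n_excluded = x$n_excluded, normalization = x$normalization,
         method = x$method)
}

#' @rdname fit_ritger_peppas
#' @param object An `rp_fit` object.
#' @method autoplot rp_fit
#' @export
autoplot.rp_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(log(.data$time_h), log(.data$fraction))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$n, intercept = log(object$k),
                         colour = "steelblue") +
    ggplot2::labs(x = "ln t", y = expression(ln(M[t] / M[infinity])),
                  title = sprintf("Ritger-Peppas fit: n = %.3f, R² = %.3f",
                                  object$n, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Fit the Ritger-Peppas model to every curve of a panel
#'
#' @inheritParams fit_ritger_peppas
#' @param curves A release-curve table with one or more `(sample_id, pH)`
#'   curves.
#' @return A tibble with one row per curve: `pH`, `sample_id`, `ef_pct`
#'   (final observed release), `duration_h`, `k`, `n`, `r_squared`,
#'   `n_points`.
#' @export
fit_rp_panel <- function(curves, window = NULL,
                         normalization = c("plateau", "total_load"),
                         method = c("loglog", "nls")) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  pieces <- split_curves(curves)
  rows <- purrr::map(pieces, function(cv) {
    fit <- fit_ritger_peppas(cv, window = window,
                             normalization = normalization, method = method)
    tibble(pH = cv$pH[1], sample_id = cv$sample_id[1],
           ef_pct = cv$released_pct[which.max(cv$time_h)],
           duration_h = max(cv$time_h),
           k = fit$k, n = fit$n, r_squared = fit$r_squared,
           n_points = fit$n_points)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$pH, .data$sample_id)
}
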