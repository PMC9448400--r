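#' Harmonic-map field value
#'
#' Evaluates the hyperbolic harmonic-map solution
#' \deqn{h = \frac{\cosh(\Phi/2) - \sinh(\Phi/2)e^{-i\alpha}}
#'             {\cosh(\Phi/2) + \sinh(\Phi/2)e^{-i\alpha}}}
#' by direct complex arithmetic. The denominator is bounded away from zero
#' for all real arguments; at \eqn{\alpha = 0} the value reduces to
#' \eqn{e^{-\Phi}}, at \eqn{\Phi = 0} it is identically 1.
#'
#' @param phi Real parameter(s) \eqn{\Phi}.
#' @param alpha Real phase(s) \eqn{\alpha}.
#' @return Complex value(s), recycled to common length.
#' @examples
#' harmonic_h(2.35, 0)   # exp(-2.35)
#' @export
harmonic_h <- function(phi, alpha) {
  if (!is.numeric(phi) || !is.numeric(alpha)) {
    abort("phi and alpha must be real numerics")
  }
  ch <- cosh(phi / 2); sh <- sinh(phi / 2)
  e <- exp(-1i * alpha)
  (ch - sh * e) / (ch + sh * e)
}

#' Harmonic-map pattern field on a frequency-time grid
#'
#' Evaluates the time-parameterized pattern field obtained from
#' [harmonic_h()] with \eqn{\alpha = 2\Omega t}, in the equivalent
#' real-arithmetic form
#' \deqn{h = \frac{i\left[e^{2\Phi}\sin(2\Omega t) - \sin(2\Omega t)
#'   - 2ie^{\Phi}\right]}{e^{2\Phi}[\cos(2\Omega t) + 1] - \cos(2\Omega t) + 1},}
#' on a regular (Omega, t) grid in dimensionless coordinates. The
#' denominator satisfies \eqn{(e^{2\Phi}-1)\cos\alpha + e^{2\Phi}+1 \ge 2}
#' for \eqn{\Phi \ge 0}, so the field has no poles; each row is periodic in
#' t with period \eqn{\pi/\Omega} (the \eqn{\Omega = 0} row is constant
#' \eqn{e^{-\Phi}}).
#'
#' The three resolution views are the modulus `|h|` (global scale), the real
#' part (differentiable scale) and the imaginary part (non-differentiable
#' scale).
#'
#' @param phi Real parameter \eqn{\Phi} (a constant over the grid).
#' @param omega_range,t_range Length-2 numeric ranges for Omega and t.
#' @param n Grid points per axis (>= 2), default 512.
#' @return An object of class `harmonic_field`: list with `phi`, `omega`
#'   and `t` axis vectors and the complex matrix `h` (rows index Omega,
#'   columns index t). Has [tidy()] and [autoplot()] methods.
#' @export
harmonic_field <- function(phi = 2.35, omega_range = c(0, 20),
                           t_range = c(0, 20), n = 512) {
  if (n < 2) abort("need at least 2 grid points per axis")
  if (diff(omega_range) < 0 || diff(t_range) < 0) abort("empty ranges")
  omega <- seq(omega_range[1], omega_range[2], length.out = n)
  t <- seq(t_range[1], t_range[2], length.out = n)
  a <- 2 * outer(omega, t)                      # alpha = 2 Omega t
  e2 <- exp(2 * phi)
  num <- 1i * (e2 * sin(a) - sin(a) - 2i * exp(phi))
  den <- e2 * (cos(a) + 1) - cos(a) + 1
  h <- num / den
  # Omega = 0 rows: t-independent limit exp(-phi), evaluated exactly
  h[omega == 0, ] <- exp(-phi)
  structure(list(phi = phi, omega = omega, t = t, h = h),
            class = "harmonic_field")
}

#' @export
print.harmonic_field <- function(x, ...) {
  cat(sprintf("Harmonic pattern field: Phi = %g, %d x %d grid, Omega in [%g, %g], t in [%g, %g]\n",
              x$phi, length(x$omega), length(x$t),
              min(x$omega), max(x$omega), min(x$t), max(x$t)))
  invisible(x)
}

#' @rdname harmonic_field
#' @param x A `harmonic_field`.
#' @param ... Unused.
#' @method tidy harmonic_field
#' @export
tidy.harmonic_field <- function(x, ...) {
  grid <- tidyr::expand_grid(omega = x$omega, t = x$t)
  hv <- as.vector(t(x$h))      # row-major: omega outer, t inner
  grid$modulus <- Mod(hv)
  grid$real <- Re(hv)
  grid$imaginary <- Im(hv)
  grid
}

#' @rdname harmonic_field
#' @param object A `harmonic_field`.
#' @param view One of `"modulus"` (global scale), `"real"` (differentiable
#'   scale), `"imaginary"` (non-differentiable scale).
#' @method autoplot harmonic_field
#' @export
autoplot.harmonic_field <- function(object,
                                    view = c("modulus", "real", "imaginary"),
                                    ...) {
  view <- match.arg(view)
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$omega,
                                  fill = .data[[view]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "t (dimensionless)", y = expression(Omega),
                  fill = view,
                  title = sprintf("pattern field, Phi = %g", object$phi)) +
    ggplot2::theme_minimal()
}

#' Residual of the harmonic-map Euler equations on a spatial grid
#'
#' Builds the field pointwise from [harmonic_h()] with a fixed phase
#' `alpha` and a user-supplied scalar field \eqn{\Phi(x, y)}, maps it to the
#' upper half-plane as \eqn{w = i h}, and evaluates the harmonic-map
#' equation residual
#' \deqn{(w - \bar w)\nabla^2 w - 2(\nabla w)^2}
#' with second-order centered differences ((\eqn{\nabla w})^2 is the sum of
#' the squared partials). When \eqn{\Phi} is harmonic the residual is pure
#' discretization error and decays as O(mesh^2); a non-harmonic \eqn{\Phi}
#' leaves an O(1) residual and is flagged.
#'
#' @param phi_fun Function `f(x, y)` returning \eqn{\Phi}; should be
#'   harmonic (e.g. affine) for the field to solve the equations.
#' @param alpha Fixed real phase.
#' @param x_range,y_range Domain ranges.
#' @param n Grid points per axis.
#' @return Max-norm of the residual over interior points, with attributes
#'   `harmonic_phi` (logical: did \eqn{\Phi} pass the discrete-Laplacian
#'   check) and `n`.
#' @export
euler_residual <- function(phi_fun, alpha = 1, x_range = c(0, 1),
                           y_range = c(0, 1), n = 64) {
  if (n < 5) abort("mesh too coarse to evaluate stencils")
  xs <- seq(x_range[1], x_range[2], length.out = n)
  ys <- seq(y_range[1], y_range[2], length.out = n)
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  Phi <- outer(xs, ys, phi_fun)
  i <- 2:(n - 1); j <- 2:(n - 1)
  lap_phi <- (Phi[i + 1, j] - 2 * Phi[i, j] + Phi[i - 1, j]) / dx^2 +
    (Phi[i, j + 1] - 2 * Phi[i, j] + Phi[i, j - 1]) / dy^2
  harm <- max(abs(lap_phi)) < 1e-6 * max(1, max(abs(Phi)))
  if (!harm) {
    warn("Phi is not harmonic on the grid; residual reported but not expected to vanish")
  }
  W <- 1i * harmonic_h(Phi, alpha)
  Wx <- (W[i + 1, j] - W[i - 1, j]) / (2 * dx)
  Wy <- (W[i, j + 1] - W[i, j - 1]) / (2 * dy)
  lap <- (W[i + 1, j] - 2 * W[i, j] + W[i - 1, j]) / dx^2 +
    (W[i, j + 1] - 2 * W[i, j] + W[i, j - 1]) / dy^2
  res <- (W[i, j] - Conj(W[i, j])) * lap - 2 * (Wx^2 + Wy^2)
  structure(max(Mod(res)), harmonic_phi = harm, n = n)
}

#' Export a pattern-field view as a delimited grid
#'
#' Writes the selected view of the field as a CSV grid with the t axis as
#' header row and the Omega axis as first column.
#'
#' @param field A [harmonic_field()].
#' @param view `"modulus"`, `"real"` or `"imaginary"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_pattern <- function(field, view = c("modulus", "real", "imaginary"),
                           path) {
  stopifnot(inherits(field, "harmonic_field"))
  view <- match.arg(view)
  vals <- switch(view, modulus = Mod(field$h), real = Re(field$h),
                 imaginary = Im(field$h))
  df <- as.data.frame(vals)
  names(df) <- formatC(field$t, digits = 10, format = "g")
  df <- cbind(omega = formatC(field$omega, digits = 10, format = "g"), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
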