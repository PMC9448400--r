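#' Parameterize a nondegenerate cubic by its Hessian roots
#'
#' A cubic \eqn{a_0X^3 + 3a_1X^2 + 3a_2X + a_3} with distinct roots is
#' parameterized by the roots \eqn{(h, \bar h)} of its Hessian — the
#' quadratic covariant \eqn{(a_0a_2-a_1^2)X^2 + (a_0a_3-a_1a_2)X +
#' (a_1a_3-a_2^2)} — together with a unit-type parameter `k_g`:
#' \deqn{X_1 = \frac{h + \bar h k}{1 + k},\quad
#'       X_2 = \frac{h + \epsilon \bar h k}{1 + \epsilon k},\quad
#'       X_3 = \frac{h + \epsilon^2 \bar h k}{1 + \epsilon^2 k},}
#' with \eqn{\epsilon = (-1 + i\sqrt3)/2} the cubic root of unity. For a
#' cubic with three distinct real roots the Hessian roots are complex
#' conjugates and `|k_g| = 1`; `h` is chosen as the root with positive
#' imaginary part (upper-half-plane convention). Roots are ordered by real
#' part, then imaginary part, and then labelled so that the three Möbius
#' preimages of `X1, X2, X3` are exactly `k_g`, \eqn{\epsilon k_g},
#' \eqn{\epsilon^2 k_g}.
#'
#' @param a0,a1,a2,a3 Real coefficients in the convention above; `a0 != 0`.
#' @return An object of class `cubic_param` with fields `coefficients`,
#'   `roots` (X1, X2, X3), `h`, `h_bar`, `k_g`, `eps` and the maximum
#'   reconstruction residual `residual`.
#' @export
parameterize_cubic <- function(a0, a1, a2, a3) {
  if (a0 == 0) abort("a0 = 0: not a cubic", class = "mfrelease_not_cubic")
  co <- c(a0, 3 * a1, 3 * a2, a3)  # descending powers
  # discriminant of a0 x^3 + b x^2 + c x + d
  b <- co[2]; cc <- co[3]; d <- co[4]
  disc <- 18 * a0 * b * cc * d - 4 * b^3 * d + b^2 * cc^2 -
    4 * a0 * cc^3 - 27 * a0^2 * d^2
  scale <- max(abs(co))^4
  if (abs(disc) < 1e-12 * scale) {
    abort("cubic has (nearly) repeated roots; Hessian parameterization degenerate",
          class = "mfrelease_degenerate_cubic")
  }
  X <- sort_complex(polish_roots(polyroot(rev(co)), co))
  # Hessian quadratic
  A <- a0 * a2 - a1^2; B <- a0 * a3 - a1 * a2; C <- a1 * a3 - a2^2
  hr <- polyroot(c(C, B, A))
  h <- if (Im(hr[1]) >= Im(hr[2])) hr[1] else hr[2]
  h_bar <- if (Im(hr[1]) >= Im(hr[2])) hr[2] else hr[1]
  eps <- complex(real = -1 / 2, imaginary = sqrt(3) / 2)
  # Mobius preimage of each root: X = (h + h_bar k)/(1 + k) => k
  kap <- (h - X) / (X - h_bar)
  k_g <- kap[1]
  # order X2, X3 so that their preimages are eps*k_g, eps^2*k_g
  r2 <- kap[2] / k_g; r3 <- kap[3] / k_g
  if (Mod(r2 - eps^2) < Mod(r2 - eps) && Mod(r3 - eps) < Mod(r3 - eps^2)) {
    X <- X[c(1, 3, 2)]
    kap <- kap[c(1, 3, 2)]
  }
  # Newton refinement of the triple against the polished roots: the map
  # (h, h_bar, k) -> (X1, X2, X3) is invertible, so the parameterization can
  # be driven to machine precision from the Hessian-root initial guess
  refined <- refine_hk(h, h_bar, k_g, X, eps)
  h <- refined$h; h_bar <- refined$h_bar; k_g <- refined$k_g
  rec <- hk_to_roots(h, h_bar, k_g, eps)
  res <- max(Mod(rec - X))
  structure(list(coefficients = c(a0 = a0, a1 = a1, a2 = a2, a3 = a3),
                 roots = X, h = h, h_bar = h_bar, k_g = k_g, eps = eps,
                 residual = res),
            class = "cubic_param")
}

sort_complex <- function(z) {
  z[order(Re(z), Im(z))]
}

# a few Newton steps to bring polyroot output to full double precision
# (co in descending powers)
polish_roots <- function(z, co) {
  dco <- co[-length(co)] * (length(co) - 1):1
  for (it in 1:3) {
    p <- ((co[1] * z + co[2]) * z + co[3]) * z + co[4]
    dp <- (dco[1] * z + dco[2]) * z + dco[3]
    step <- p / dp
    step[!is.finite(step)] <- 0
    z <- z - step
  }
  z
}

# Newton iteration on F(h, h_bar, k) = reconstruction - X with the analytic
# complex Jacobian of the Mobius system
refine_hk <- function(h, h_bar, k_g, X, eps) {
  e <- c(1 + 0i, eps, eps^2)
  for (it in 1:4) {
    den <- 1 + e * k_g
    rec <- (h + h_bar * e * k_g) / den
    F <- rec - X
    if (max(Mod(F)) < 1e-14 * max(1, Mod(X))) break
    J <- cbind(1 / den, e * k_g / den, e * (h_bar - rec) / den)
    delta <- tryCatch(solve(J, F), error = function(err) NULL)
    if (is.null(delta)) break
    h <- h - delta[1]; h_bar <- h_bar - delta[2]; k_g <- k_g - delta[3]
  }
  list(h = h, h_bar = h_bar, k_g = k_g)
}

# reconstruct the three roots from the Hessian-root parameterization
hk_to_roots <- function(h, h_bar, k_g, eps = complex(real = -0.5, imaginary = sqrt(3) / 2)) {
  e <- c(1 + 0i, eps, eps^2)
  (h + h_bar * e * k_g) / (1 + e * k_g)
}

#' @export
print.cubic_param <- function(x, ...) {
  cat("Cubic parameterization via Hessian roots\n")
  cat("  roots:", format(x$roots, digits = 6), "\n")
  cat("  h =", format(x$h, digits = 6), " k_g =", format(x$k_g, digits = 6),
      sprintf(" (reconstruction residual %.2e)\n", x$residual))
  invisible(x)
}

#' Homographic group action on roots and on the Hessian triple
#'
#' `act_on_roots()` applies the Möbius (homographic) map
#' \eqn{X \mapsto (aX + b)/(cX + d)} to each root; `act_on_hk()` applies the
#' induced action on the triple \eqn{(h, \bar h, k)}:
#' \deqn{h \mapsto \frac{ah+b}{ch+d},\quad
#'       \bar h \mapsto \frac{a\bar h+b}{c\bar h+d},\quad
#'       k \mapsto \frac{c\bar h + d}{c h + d}\,k.}
#' The two routes commute with the parameterization: transforming the roots
#' and re-deriving the triple gives the transformed triple.
#'
#' @param x For `act_on_roots()`: a complex vector of roots or a
#'   `cubic_param` object. For `act_on_hk()`: a `cubic_param` object or a
#'   list with fields `h`, `h_bar`, `k_g`.
#' @param m The transformation, as `c(a, b, c, d)` or a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`; must satisfy `a*d - b*c != 0`.
#' @return Transformed roots (complex vector) or transformed triple (list
#'   with `h`, `h_bar`, `k_g`).
#' @export
act_on_roots <- function(x, m) {
  m <- as_mobius(m)
  z <- if (inherits(x, "cubic_param")) x$roots else x
  den <- m[3] * z + m[4]
  if (any(Mod(den) < 1e-14 * max(1, Mod(z)))) {
    abort("pole hit: a root equals -d/c", class = "mfrelease_pole")
  }
  (m[1] * z + m[2]) / den
}

#' @rdname act_on_roots
#' @export
act_on_hk <- function(x, m) {
  m <- as_mobius(m)
  h <- x$h; h_bar <- x$h_bar; k_g <- x$k_g
  den <- m[3] * h + m[4]; den_bar <- m[3] * h_bar + m[4]
  if (min(Mod(den), Mod(den_bar)) < 1e-14 * max(1, Mod(h))) {
    abort("pole hit: h or h_bar equals -d/c", class = "mfrelease_pole")
  }
  list(h = (m[1] * h + m[2]) / den,
       h_bar = (m[1] * h_bar + m[2]) / den_bar,
       k_g = k_g * den_bar / den)
}

as_mobius <- function(m) {
  if (is.matrix(m)) m <- c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
  if (length(m) != 4) abort("transformation must be (a, b, c, d)")
  if (abs(m[1] * m[4] - m[2] * m[3]) < 1e-14) {
    abort("singular transformation: ad - bc = 0", class = "mfrelease_singular")
  }
  m
}

#' Infinitesimal generators of the synchronization group
#'
#' The three vector fields on \eqn{(h, \bar h, k)}
#' \deqn{B_1 = \partial_h + \partial_{\bar h},\quad
#'       B_2 = h\partial_h + \bar h\partial_{\bar h},\quad
#'       B_3 = h^2\partial_h + \bar h^2\partial_{\bar h} + (h-\bar h)k\partial_k,}
#' which close the sl(2, R) bracket relations
#' \eqn{[B_1,B_2]=B_1,\ [B_2,B_3]=B_3,\ [B_3,B_1]=-2B_2}.
#'
#' Each generator is returned as a function mapping a point
#' `c(h = , h_bar = , k = )` (complex) to its coefficient vector on
#' \eqn{(\partial_h, \partial_{\bar h}, \partial_k)}.
#'
#' @return A named list of three vector-field functions `B1`, `B2`, `B3`.
#' @export
sl2r_generators <- function() {
  list(
    B1 = function(p) c(1 + 0i, 1 + 0i, 0 + 0i),
    B2 = function(p) c(p[["h"]], p[["h_bar"]], 0 + 0i),
    B3 = function(p) c(p[["h"]]^2, p[["h_bar"]]^2,
                       (p[["h"]] - p[["h_bar"]]) * p[["k"]])
  )
}

# commutator of two vector fields (coefficient-function representation),
# evaluated at point p by central differences (exact for polynomial
# coefficients of degree <= 2, which covers the sl(2,R) generators)
vf_commutator <- function(A, B, p, h_step = 1e-4) {
  vars <- c("h", "h_bar", "k")
  JA <- vf_jacobian(A, p, h_step)
  JB <- vf_jacobian(B, p, h_step)
  a <- A(p); b <- B(p)
  # [A,B]_j = sum_i (A_i d_i B_j - B_i d_i A_j)
  as.vector(JB %*% a - JA %*% b)
}

vf_jacobian <- function(F, p, h_step) {
  vars <- c("h", "h_bar", "k")
  J <- matrix(0 + 0i, 3, 3)
  for (i in seq_along(vars)) {
    pp <- p; pm <- p
    pp[[vars[i]]] <- pp[[vars[i]]] + h_step
    pm[[vars[i]]] <- pm[[vars[i]]] - h_step
    J[, i] <- (F(pp) - F(pm)) / (2 * h_step)
  }
  J
}

#' Verify the sl(2, R) bracket relations of the generators
#'
#' Evaluates the commutators \eqn{[B_1,B_2]-B_1}, \eqn{[B_2,B_3]-B_3} and
#' \eqn{[B_3,B_1]+2B_2} at a set of points and returns the maximum
#' coefficient defect. For the generators of [sl2r_generators()] the defect
#' is at roundoff level (< 1e-9); perturbing a generator yields an O(1)
#' defect.
#'
#' @param gens A list of three vector fields as returned by
#'   [sl2r_generators()].
#' @param points Optional list of evaluation points (named complex vectors
#'   with entries `h`, `h_bar`, `k`); defaults to a small deterministic set
#'   of generic points.
#' @return Maximum absolute defect over points and relations.
#' @export
verify_sl2r_structure <- function(gens = sl2r_generators(), points = NULL) {
  if (is.null(points)) {
    points <- list(
      c(h = 0.3 + 1.1i, h_bar = 0.3 - 1.1i, k = exp(0.7i)),
      c(h = -1.2 + 0.4i, h_bar = -1.2 - 0.4i, k = exp(-1.9i)),
      c(h = 2.5 + 2.2i, h_bar = 2.5 - 2.2i, k = 0.8 * exp(2.4i)),
      c(h = -0.6 + 3.0i, h_bar = 0.2 - 1.4i, k = 1.7 + 0.3i)
    )
  }
  defect <- 0
  for (p in points) {
    d1 <- vf_commutator(gens$B1, gens$B2, p) - gens$B1(p)
    d2 <- vf_commutator(gens$B2, gens$B3, p) - gens$B3(p)
    d3 <- vf_commutator(gens$B3, gens$B1, p) + 2 * gens$B2(p)
    defect <- max(defect, Mod(d1), Mod(d2), Mod(d3))
  }
  defect
}

#' Invariant 1-forms of the synchronization group
#'
#' `one_forms_complex()` evaluates, at \eqn{(h, \bar h, k)} with
#' displacement \eqn{(dh, d\bar h, dk)},
#' \deqn{\omega_1 = \frac{dh}{(h-\bar h)k},\quad
#'   \omega_2 = -i\Big(\frac{dk}{k} - \frac{dh + d\bar h}{h - \bar h}\Big),\quad
#'   \omega_3 = -\frac{k\, d\bar h}{h-\bar h}.}
#' `one_forms_real()` evaluates the real-coordinate forms at
#' \eqn{h = u + iv,\ k = e^{i\theta}}:
#' \deqn{\Omega_1 = d\theta + \frac{du}{v},\quad
#'   \Omega_2 = \cos\theta\frac{du}{v} + \sin\theta\frac{dv}{v},\quad
#'   \Omega_3 = -\sin\theta\frac{du}{v} + \cos\theta\frac{dv}{v}.}
#' They satisfy \eqn{-\Omega_1^2 + \Omega_2^2 + \Omega_3^2 =
#' -(d\theta + du/v)^2 + (du^2 + dv^2)/v^2} identically.
#'
#' @param h,h_bar,k_g Complex coordinates (`h != h_bar`).
#' @param dh,dh_bar,dk Complex displacements.
#' @return A named list of the three form values.
#' @export
one_forms_complex <- function(h, h_bar, k_g, dh, dh_bar, dk) {
  if (Mod(h - h_bar) < 1e-14) {
    abort("h = h_bar: degenerate point", class = "mfrelease_degenerate_point")
  }
  list(omega1 = dh / ((h - h_bar) * k_g),
       omega2 = -1i * (dk / k_g - (dh + dh_bar) / (h - h_bar)),
       omega3 = -k_g * dh_bar / (h - h_bar))
}

#' @rdname one_forms_complex
#' @param point Named numeric vector or list with `u`, `v` (> 0), `theta`.
#' @param displacement Named numeric vector or list with `du`, `dv`,
#'   `dtheta`.
#' @export
one_forms_real <- function(point, displacement) {
  u <- point[["u"]]; v <- point[["v"]]; th <- point[["theta"]]
  if (v <= 0) abort("v must be > 0 (upper half-plane)")
  du <- displacement[["du"]]; dv <- displacement[["dv"]]
  dth <- displacement[["dtheta"]]
  list(Omega1 = dth + du / v,
       Omega2 = cos(th) * du / v + sin(th) * dv / v,
       Omega3 = -sin(th) * du / v + cos(th) * dv / v)
}

#' Hyperbolic metric on the extended (u, v, theta) space
#'
#' Unconstrained mode evaluates
#' \deqn{ds^2 = -(d\theta + du/v)^2 + (du^2 + dv^2)/v^2;}
#' constrained mode enforces the angle-of-parallelism condition
#' \eqn{d\theta = -du/v} (vanishing of the first form), under which the
#' metric reduces to the Poincaré upper-half-plane metric
#' \eqn{(du^2 + dv^2)/v^2}.
#'
#' @inheritParams one_forms_real
#' @param constrained Logical; enforce the parallelism constraint.
#' @return The squared line element (scalar).
#' @export
metric_ds2 <- function(point, displacement, constrained = FALSE) {
  v <- point[["v"]]
  if (v <= 0) abort("v must be > 0 (upper half-plane)")
  du <- displacement[["du"]]; dv <- displacement[["dv"]]
  if (constrained) {
    return((du^2 + dv^2) / v^2)
  }
  Om <- one_forms_real(point, displacement)
  -Om$Omega1^2 + Om$Omega2^2 + Om$Omega3^2
}

#' Run the full geometry identity suite
#'
#' Fuzz-tests the Hessian-root parameterization, the two group-action
#' routes, the bracket relations and the metric identities on seeded random
#' inputs, returning the worst defect of each family.
#'
#' @param n_cubics Number of random nondegenerate cubics.
#' @param seed Integer seed.
#' @return A tibble with columns `check` and `max_defect`.
#' @export
geometry_selftest <- function(n_cubics = 1000, seed = 1) {
  set.seed(seed)
  rec_res <- act_res <- 0
  n_done <- 0
  while (n_done < n_cubics) {
    r <- sort(runif(3, -3, 3))
    if (min(diff(r)) < 0.05) next   # keep away from degeneracy
    a0 <- runif(1, 0.5, 2)
    # cubic with roots r: a0 (x-r1)(x-r2)(x-r3)
    co <- a0 * c(1, -sum(r), sum(r * c(r[2], r[3], r[1])), -prod(r))
    cp <- parameterize_cubic(co[1], co[2] / 3, co[3] / 3, co[4])
    rec_res <- max(rec_res, cp$residual)
    m <- runif(4, -2, 2)
    if (abs(m[1] * m[4] - m[2] * m[3]) < 0.1) m[1] <- m[1] + 1
    ok <- !any(Mod(m[3] * cp$roots + m[4]) < 0.2) &&
      min(Mod(m[3] * c(cp$h, cp$h_bar) + m[4])) > 0.2
    if (ok) {
      direct <- act_on_hk(cp, m)
      via_roots <- act_on_roots(cp, m)
      rec <- hk_to_roots(direct$h, direct$h_bar, direct$k_g)
      act_res <- max(act_res, max(Mod(sort_complex(rec) - sort_complex(via_roots))))
    }
    n_done <- n_done + 1
  }
  bracket <- verify_sl2r_structure()
  met_res <- 0
  for (i in 1:100) {
    pt <- c(u = runif(1, -2, 2), v = runif(1, 0.1, 3),
            theta = runif(1, -pi, pi))
    du <- runif(1, -1, 1); dv <- runif(1, -1, 1)
    disp <- c(du = du, dv = dv, dtheta = -du / pt[["v"]])
    met_res <- max(met_res, abs(metric_ds2(pt, disp) -
                                  metric_ds2(pt, disp, constrained = TRUE)))
  }
  tibble(check = c("hessian_reconstruction", "group_action_consistency",
                   "bracket_relations", "metric_constraint_identity"),
         max_defect = c(rec_res, act_res, bracket, met_res))
}
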