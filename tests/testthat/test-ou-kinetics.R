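test_that("closed-form moments behave at the limits", {
  p <- ou_params(D = 1, eta = 0.5, x0 = 1)
  m0 <- ou_moments(0, p)
  expect_equal(m0$mean, 1)
  expect_equal(m0$variance, 0)
  # variance saturates at D/eta
  expect_equal(ou_moments(1e4, p)$variance, 2, tolerance = 1e-12)
  # mean decays exponentially
  p1 <- ou_params(D = 0.3, eta = 1, x0 = 1)
  expect_equal(ou_moments(1, p1)$mean, exp(-1), tolerance = 1e-12)
  # saturation in the stiff-relaxation limit
  expect_equal(ou_moments(0.5, ou_params(D = 2, eta = 50))$variance,
               2 / 50, tolerance = 1e-6)
})

test_that("the density integrates to one and reproduces its moments by quadrature", {
  cases <- list(ou_params(D = 1, eta = 0.5, x0 = 1),
                ou_params(D = 4, eta = 0.05, x0 = -2),
                ou_params(D = 0.2, eta = 2, x0 = 0))
  for (p in cases) {
    for (t in c(0.1, 1, 10)) {
      m <- ou_moments(t, p)
      s <- sqrt(m$variance)
      lims <- c(m$mean - 10 * s, m$mean + 10 * s)
      total <- integrate(function(x) ou_density(x, t, p), lims[1], lims[2],
                         rel.tol = 1e-10)$value
      expect_equal(total, 1, tolerance = 1e-8)
      mu <- integrate(function(x) x * ou_density(x, t, p), lims[1], lims[2],
                      rel.tol = 1e-10)$value
      v <- integrate(function(x) (x - mu)^2 * ou_density(x, t, p),
                     lims[1], lims[2], rel.tol = 1e-10)$value
      expect_equal(mu, m$mean, tolerance = 1e-8)
      expect_equal(v, m$variance, tolerance = 1e-8)
    }
  }
  expect_error(ou_density(0, 0, cases[[1]]),
               class = "mfrelease_degenerate_density")
})

test_that("the density solves the Fokker-Planck equation at second order", {
  p <- ou_params(D = 1, eta = 0.5, x0 = 1)
  grids <- function(nf) {
    list(x = seq(-8, 9, length.out = 80 * nf + 1),
         t = seq(1, 2, length.out = 40 * nf + 1))
  }
  g1 <- grids(1); g2 <- grids(2)
  r1 <- fokker_planck_residual(p, x = g1$x, t = g1$t)
  r2 <- fokker_planck_residual(p, x = g2$x, t = g2$t)
  expect_lt(abs(r1 / r2 - 4), 0.3)
  # negative control: density with the wrong relaxation rate
  wrong <- function(x, t) ou_density(x, t, ou_params(D = 1, eta = 1, x0 = 1))
  r_bad <- fokker_planck_residual(p, x = g2$x, t = g2$t, density = wrong)
  expect_gt(r_bad, 100 * r2)
})

test_that("the advection-only limit transports a narrow Gaussian", {
  # D = 0: rho(x, t) = N(x0 e^{-eta t}, s0 e^{-eta t}) solves the pure-drift law
  p0 <- ou_params(D = 0, eta = 0.5, x0 = 1)
  s0 <- 0.3
  transported <- function(x, t) {
    stats::dnorm(x, mean = exp(-0.5 * t), sd = s0 * exp(-0.5 * t))
  }
  r <- fokker_planck_residual(p0, x = seq(-1, 2, length.out = 601),
                              t = seq(0.2, 0.7, length.out = 201),
                              density = transported)
  expect_lt(r, 1e-2)
})

test_that("scale-transition algebra round-trips and collapses where it should", {
  sp <- scale_params(lambda = 0.7, dt_res = 0.25, f_alpha = 1.3)
  D <- 3.2
  expect_equal(D_from_lambda(lambda_from_D(D, sp), sp), D, tolerance = 1e-15)
  # dt = 1: lambda = D/2 whatever the spectrum
  expect_equal(lambda_from_D(5, scale_params(dt_res = 1, f_alpha = 0.77)), 2.5)
  # f(alpha) = 2: exponent vanishes, lambda = D/2 independent of dt
  expect_equal(lambda_from_D(5, scale_params(dt_res = 0.001, f_alpha = 2)), 2.5)
  expect_error(scale_params(dt_res = 0), "dt_res")
})

test_that("hydrodynamic diagnostics recover the Gaussian closed forms", {
  x <- seq(-4, 4, length.out = 801)
  # uniform density: both velocities and the potential vanish
  u <- hydrodynamic_diagnostics(rep(0.125, 801), x = x)
  expect_equal(max(abs(u$v_f)), 0)
  expect_equal(max(abs(u$q_potential)), 0, tolerance = 1e-6)
  # unit Gaussian with chi = 1: V_F = -x, Q = chi^2 (1 - x^2 / 2)
  rho <- stats::dnorm(x)
  g <- hydrodynamic_diagnostics(rho, x = x, sp = scale_params(lambda = 1, dt_res = 1))
  inner <- abs(x) < 3
  expect_lt(max(abs(g$v_f[inner] + x[inner])), 1e-3)
  expect_lt(max(abs(g$q_potential[inner] - (1 - x[inner]^2 / 2))), 1e-3)
  # phase field drives the differentiable velocity: s = x^2/2 -> V_D = 2 chi x
  g2 <- hydrodynamic_diagnostics(rho, x = x, s_phase = x^2 / 2)
  expect_lt(max(abs(g2$v_d[inner] - 2 * x[inner])), 1e-3)
  expect_error(hydrodynamic_diagnostics(c(1, 0, 1), x = c(1, 2, 3)), "positive")
})

test_that("the particle ensemble is seeded, stable and deterministic in the D = 0 limit", {
  p <- ou_params(D = 0, eta = 1, x0 = 1)
  ens <- simulate_ou_ensemble(p, n_particles = 10, t_grid = c(0.5, 1), seed = 1)
  expect_equal(unique(round(ens$snapshots$x[ens$snapshots$t == 1], 6)),
               round(exp(-1), 6), tolerance = 1e-2)
  expect_lt(abs(ens$moments$mean[2] - exp(-1)), 5e-3)  # integrator-order bias only

  pd <- ou_params(D = 1, eta = 1, x0 = 1)
  a <- simulate_ou_ensemble(pd, 100, t_grid = 1, seed = 42)
  b <- simulate_ou_ensemble(pd, 100, t_grid = 1, seed = 42)
  c <- simulate_ou_ensemble(pd, 100, t_grid = 1, seed = 43)
  expect_identical(a$snapshots$x, b$snapshots$x)
  expect_false(identical(a$snapshots$x, c$snapshots$x))
  expect_error(simulate_ou_ensemble(pd, 10, t_grid = 1, step = 0.6, seed = 1),
               class = "mfrelease_unstable_step")
  expect_error(simulate_ou_ensemble(pd, 10, t_grid = 1), "seed")
})

test_that("ensemble moments agree with the closed form at moderate size", {
  p <- ou_params(D = 1, eta = 1, x0 = 1)
  ens <- simulate_ou_ensemble(p, n_particles = 2e4, t_grid = c(0.5, 1, 2),
                              seed = 9)
  m <- ou_moments(ens$moments$t, p)
  expect_true(all(abs(ens$moments$mean - m$mean) < 3 * ens$moments$se_mean +
                    2e-3))
  se_var <- m$variance * sqrt(2 / (2e4 - 1))
  expect_true(all(abs(ens$moments$variance - m$variance) < 3 * se_var + 1e-2))
})

test_that("the release law saturates, vanishes at zero and has early exponent 1/2", {
  p <- ou_params(D = 2, eta = 0.01)
  expect_equal(release_from_ou(0, p), 0)
  expect_equal(release_from_ou(1e6, p), sqrt(200), tolerance = 1e-10)
  # numerical log-log slope well inside the early-time regime
  t1 <- 1e-4; t2 <- 2e-4
  slope <- (log(release_from_ou(t2, p)) - log(release_from_ou(t1, p))) /
    (log(t2) - log(t1))
  expect_lt(abs(slope - 0.5), 1e-3)
})
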