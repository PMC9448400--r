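test_that("the map reduces to exponentials at special phases", {
  for (phi in c(0.5, 1.2, 2.35)) {
    expect_equal(harmonic_h(phi, 0), complex(real = exp(-phi)),
                 tolerance = 1e-14)
    # alpha = pi flips the sign of the sinh term: h = e^{+phi}
    expect_equal(harmonic_h(phi, pi), complex(real = exp(phi)),
                 tolerance = 1e-12)
  }
  expect_equal(harmonic_h(0, c(0.3, 2, 5)), rep(1 + 0i, 3))
})

test_that("the grid field matches the direct evaluation everywhere", {
  f <- harmonic_field(phi = 2.35, omega_range = c(0, 20),
                      t_range = c(0, 20), n = 64)
  direct <- outer(f$omega, f$t, function(om, tt) harmonic_h(2.35, 2 * om * tt))
  expect_lt(max(Mod(f$h - direct)), 1e-12)
  # t = 0 column collapses to e^{-Phi}
  expect_equal(f$h[, 1], rep(complex(real = exp(-2.35)), 64), tolerance = 1e-14)
  expect_equal(Re(f$h[5, 1]), 0.09537, tolerance = 1e-4)
})

test_that("rows are periodic in t with period pi / Omega", {
  phi <- 2.35
  for (om in c(0.7, 3, 11)) {
    t <- c(0.3, 1.1, 4.2)
    expect_equal(harmonic_h(phi, 2 * om * t),
                 harmonic_h(phi, 2 * om * (t + pi / om)), tolerance = 1e-9)
  }
})

test_that("the denominator is bounded below by 2, so the field has no poles", {
  f <- harmonic_field(phi = 2.35, n = 512)
  a <- 2 * outer(f$omega, f$t)
  den <- exp(2 * 2.35) * (cos(a) + 1) - cos(a) + 1
  expect_gte(min(den), 2)
  expect_true(all(is.finite(Mod(f$h))))
})

test_that("the Euler residual vanishes at second order for harmonic Phi", {
  r1 <- euler_residual(function(x, y) 0.3 * x + 0.4 * y, alpha = 1, n = 41)
  r2 <- euler_residual(function(x, y) 0.3 * x + 0.4 * y, alpha = 1, n = 81)
  expect_lt(abs(r1 / r2 - 4), 0.3)
  # constant Phi: gradient-free field, residual exactly zero
  r0 <- euler_residual(function(x, y) 0 * x + 1.7, alpha = 2, n = 21)
  expect_equal(as.numeric(r0), 0)
  # non-harmonic Phi is flagged and leaves an O(1) residual
  expect_warning(rbad <- euler_residual(function(x, y) x^2, alpha = 1, n = 41),
                 "not harmonic")
  expect_gt(rbad, 1e-3)
  expect_false(attr(rbad, "harmonic_phi"))
})

test_that("pattern export writes finite grids with the expected views", {
  f <- harmonic_field(phi = 2.35, omega_range = c(0, 5), t_range = c(0, 5),
                      n = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  export_pattern(f, "modulus", path)
  grid <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(dim(grid), c(10, 11))  # omega column + 10 t columns
  expect_true(all(is.finite(as.matrix(grid[, -1]))))
  # imaginary part vanishes on the t = 0 column
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_pattern(f, "imaginary", path2)
  grid2 <- readr::read_csv(path2, show_col_types = FALSE)
  expect_equal(grid2[[2]], rep(0, 10), tolerance = 1e-14)
})

test_that("the field is self-similar under range rescaling", {
  # h depends on Omega * t only, so the (0,200)^2 field subsampled onto
  # (0,20)^2 must reproduce the small-range field on the shared grid
  small <- harmonic_field(phi = 2.35, omega_range = c(0, 20),
                          t_range = c(0, 20), n = 65)
  big <- harmonic_field(phi = 2.35, omega_range = c(0, 200),
                        t_range = c(0, 200), n = 641)
  expect_equal(big$omega[1:65], small$omega, tolerance = 1e-12)
  expect_lt(max(Mod(big$h[1:65, 1:65] - small$h)), 1e-10)
})

test_that("tidy and autoplot expose the three resolution views", {
  f <- harmonic_field(phi = 1, omega_range = c(0, 2), t_range = c(0, 2), n = 8)
  td <- tidy(f)
  expect_tibble_cols(td, c("omega", "t", "modulus", "real", "imaginary"))
  expect_equal(nrow(td), 64)
  expect_equal(td$modulus, Mod(td$real + 1i * td$imaginary), tolerance = 1e-12)
  expect_s3_class(autoplot(f, "imaginary"), "ggplot")
})
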