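test_that("known cubics reconstruct through their Hessian roots", {
  # roots {-1, 0, 1}: x^3 - x
  cp <- parameterize_cubic(1, 0, -1 / 3, 0)
  expect_lt(cp$residual, 1e-10)
  expect_equal(sort(Re(cp$roots)), c(-1, 0, 1), tolerance = 1e-10)
  expect_gt(Im(cp$h), 0)
  expect_equal(Mod(cp$k_g), 1, tolerance = 1e-10)   # real-rooted cubic
  # roots {1, 2, 3}: x^3 - 6x^2 + 11x - 6
  cp2 <- parameterize_cubic(1, -2, 11 / 3, -6)
  expect_lt(cp2$residual, 1e-10)
  expect_equal(sort(Re(cp2$roots)), c(1, 2, 3), tolerance = 1e-9)
})

test_that("degenerate cubics are rejected", {
  # (x - 1)^2 (x + 2) = x^3 - 3x + 2
  expect_error(parameterize_cubic(1, 0, -1, 2),
               class = "mfrelease_degenerate_cubic")
  expect_error(parameterize_cubic(0, 1, 1, 1), class = "mfrelease_not_cubic")
})

test_that("the homographic action is consistent along both routes", {
  cp <- parameterize_cubic(1, 0, -1 / 3, 0)
  # identity leaves everything unchanged
  id <- act_on_hk(cp, c(1, 0, 0, 1))
  expect_equal(id$h, cp$h)
  expect_equal(id$k_g, cp$k_g)
  # pure scaling: roots scale, k_g invariant
  sc <- act_on_roots(cp, c(2, 0, 0, 1))
  expect_equal(sc, 2 * cp$roots)
  expect_equal(act_on_hk(cp, c(2, 0, 0, 1))$k_g, cp$k_g)
  # random transforms: transformed triple reconstructs transformed roots
  set.seed(8)
  for (i in 1:25) {
    m <- runif(4, -2, 2)
    if (abs(m[1] * m[4] - m[2] * m[3]) < 0.1) m[1] <- m[1] + 1
    if (any(Mod(m[3] * cp$roots + m[4]) < 0.05)) next
    tr <- act_on_hk(cp, m)
    rec <- sort(Re(mfrelease:::hk_to_roots(tr$h, tr$h_bar, tr$k_g)))
    direct <- sort(Re(act_on_roots(cp, m)))
    expect_equal(rec, direct, tolerance = 1e-9)
  }
  expect_error(act_on_roots(cp, c(1, 2, 2, 4)), class = "mfrelease_singular")
  expect_error(act_on_roots(cp, c(2, 1, 1, 1)), class = "mfrelease_pole")
})

test_that("the generators close the sl(2, R) bracket relations", {
  expect_lt(verify_sl2r_structure(), 1e-9)
  # antisymmetry of the commutator
  g <- sl2r_generators()
  p <- c(h = 0.5 + 1.2i, h_bar = 0.5 - 1.2i, k = exp(0.3i))
  ab <- mfrelease:::vf_commutator(g$B1, g$B2, p)
  ba <- mfrelease:::vf_commutator(g$B2, g$B1, p)
  expect_equal(ab, -ba, tolerance = 1e-12)
  # negative control: perturbing B3 by d/dk breaks the algebra at O(1)
  gbad <- g
  gbad$B3 <- function(p) g$B3(p) + c(0, 0, 1)
  expect_gt(verify_sl2r_structure(gbad), 0.1)
})

test_that("the 1-forms read off the real coordinates correctly", {
  pt <- c(u = 0.4, v = 1.5, theta = 0.6)
  pure_rot <- one_forms_real(pt, c(du = 0, dv = 0, dtheta = 0.37))
  expect_equal(pure_rot$Omega1, 0.37)
  expect_equal(pure_rot$Omega2, 0)
  expect_equal(pure_rot$Omega3, 0)
  pt0 <- c(u = 0.4, v = 2, theta = 0)
  at0 <- one_forms_real(pt0, c(du = 0.3, dv = 0.5, dtheta = 0))
  expect_equal(at0$Omega2, 0.3 / 2)
  expect_equal(at0$Omega3, 0.5 / 2)
})

test_that("complex and real 1-forms agree on the half-plane chart", {
  # h = u + iv, k = e^{i theta}: omega2 must equal dtheta + du / v
  set.seed(15)
  for (i in 1:20) {
    u <- runif(1, -2, 2); v <- runif(1, 0.2, 3); th <- runif(1, -pi, pi)
    du <- runif(1, -1, 1); dv <- runif(1, -1, 1); dth <- runif(1, -1, 1)
    om <- one_forms_complex(
      h = complex(real = u, imaginary = v),
      h_bar = complex(real = u, imaginary = -v),
      k_g = exp(1i * th),
      dh = complex(real = du, imaginary = dv),
      dh_bar = complex(real = du, imaginary = -dv),
      dk = 1i * exp(1i * th) * dth
    )
    Om <- one_forms_real(c(u = u, v = v, theta = th),
                         c(du = du, dv = dv, dtheta = dth))
    expect_equal(Re(om$omega2), Om$Omega1, tolerance = 1e-12)
    expect_equal(Mod(Im(om$omega2)), 0, tolerance = 1e-12)
  }
  expect_error(one_forms_complex(1 + 0i, 1 + 0i, 1, 0, 0, 0),
               class = "mfrelease_degenerate_point")
})

test_that("the extended metric reduces to the Poincare half-plane form", {
  expect_equal(metric_ds2(c(u = 0, v = 1, theta = 0.2),
                          c(du = 0.1, dv = 0, dtheta = -0.1)), 0.01)
  expect_equal(metric_ds2(c(u = 0, v = 2, theta = 1.1),
                          c(du = 0, dv = 0.2, dtheta = 0)), 0.01)
  # quadratic-form identity against the 1-forms on random tangents
  set.seed(21)
  for (i in 1:50) {
    pt <- c(u = runif(1, -2, 2), v = runif(1, 0.1, 3),
            theta = runif(1, -pi, pi))
    dd <- c(du = runif(1, -1, 1), dv = runif(1, -1, 1),
            dtheta = runif(1, -1, 1))
    Om <- one_forms_real(pt, dd)
    expect_equal(metric_ds2(pt, dd),
                 -Om$Omega1^2 + Om$Omega2^2 + Om$Omega3^2,
                 tolerance = 1e-12)
    # under the parallelism constraint both modes agree
    dd_c <- dd; dd_c[["dtheta"]] <- -dd[["du"]] / pt[["v"]]
    expect_equal(metric_ds2(pt, dd_c),
                 metric_ds2(pt, dd_c, constrained = TRUE),
                 tolerance = 1e-12)
  }
  expect_error(metric_ds2(c(u = 0, v = -1, theta = 0),
                          c(du = 1, dv = 0, dtheta = 0)), "v must be")
})

test_that("the full geometry self-test passes its defect budgets", {
  res <- geometry_selftest(n_cubics = 200, seed = 2)
  budgets <- c(hessian_reconstruction = 1e-10,
               group_action_consistency = 1e-9,
               bracket_relations = 1e-9,
               metric_constraint_identity = 1e-12)
  expect_true(all(res$max_defect < budgets[res$check]))
})
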