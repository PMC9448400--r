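test_that("rp_predict evaluates the power law and caps at complete release", {
  expect_equal(rp_predict(0.1, 0.5, 4), 0.2)
  expect_equal(rp_predict(0.3, 0.7, 0), 0)
  expect_equal(rp_predict(0.01, 1, 10), 0.1)
  expect_warning(capped <- rp_predict(0.5, 1, 10), "capped")
  expect_equal(as.numeric(capped), 1)
  expect_equal(attr(capped, "uncapped"), 5)
  expect_error(rp_predict(0.1, 0.5, -1), ">= 0")
  expect_error(rp_predict(-0.1, 0.5, 1), "> 0")
})

test_that("noiseless power-law curves are recovered exactly in both modes", {
  for (k in c(0.005, 0.02, 0.05)) {
    for (n in c(0.25, 0.45, 0.548, 0.7)) {
      fit <- fit_ritger_peppas(power_law_curve(k, n),
                               normalization = "total_load")
      expect_equal(fit$n, n, tolerance = 1e-10)
      expect_equal(fit$k, k, tolerance = 1e-10)
      expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    }
  }
  # direct nonlinear mode agrees on model-true data
  fit_nls <- fit_ritger_peppas(power_law_curve(0.05, 0.548),
                               normalization = "total_load", method = "nls")
  expect_equal(fit_nls$n, 0.548, tolerance = 1e-8)
  expect_equal(fit_nls$k, 0.05, tolerance = 1e-8)
})

test_that("the exponent is invariant under release-axis rescaling with plateau normalization", {
  curve <- power_law_curve(0.05, 0.5)
  scaled <- dplyr::mutate(curve, released_pct = released_pct * 0.37)
  f1 <- fit_ritger_peppas(curve, normalization = "plateau")
  f2 <- fit_ritger_peppas(scaled, normalization = "plateau")
  expect_equal(f1$n, f2$n, tolerance = 1e-12)
  expect_equal(f1$n, 0.5, tolerance = 1e-12)
})

test_that("the exponent survives 2% multiplicative increment noise", {
  cfg <- panel_config(generator = "ritger_peppas", noise_rel = 0.02, seed = 5)
  panel <- generate_panel(cfg)
  truth <- attr(panel, "truth")
  fits <- fit_rp_panel(panel)
  joined <- dplyr::inner_join(fits, truth, by = c("pH", "sample_id"))
  expect_equal(nrow(joined), 9)
  expect_true(all(abs(joined$n - joined$n_true) < 0.02))
})

test_that("degenerate inputs flag or fail as appropriate", {
  const <- tibble::tibble(sample_id = "A", pH = 7, time_h = c(1, 2, 4, 8),
                          released_pct = rep(40, 4))
  expect_warning(fit <- fit_ritger_peppas(const), "outside")
  expect_equal(fit$n, 0)

  few <- tibble::tibble(sample_id = "A", pH = 7, time_h = c(0, 1, 2),
                        released_pct = c(0, 5, 9))
  expect_error(fit_ritger_peppas(few), "3 usable")

  # window restricting the classical <= 60% release rule
  curve <- power_law_curve(0.05, 0.5, times = c(1, 4, 9, 16, 36, 64, 100, 144))
  fit60 <- fit_ritger_peppas(curve, window = c(0, 100),
                             normalization = "total_load")
  expect_equal(fit60$window[2], 100)
  expect_equal(fit60$n, 0.5, tolerance = 1e-10)
})

test_that("panel reports carry one row per curve with plateau and duration", {
  cfg <- panel_config(generator = "ritger_peppas", noise_rel = 0, seed = 1)
  panel <- generate_panel(cfg)
  rep <- fit_rp_panel(panel)
  expect_tibble_cols(rep, c("pH", "sample_id", "ef_pct", "duration_h",
                            "k", "n", "r_squared"))
  expect_equal(nrow(rep), 9)
  expect_equal(rep$ef_pct[rep$pH == 2],
               c(95.2, 94.3, 94.1), tolerance = 1e-10)
  expect_equal(rep$duration_h[rep$pH == 7.4], c(218, 264, 218))
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- fit_ritger_peppas(power_law_curve(0.05, 0.5))
  td <- tidy(fit)
  expect_equal(td$term, c("k", "n"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 7)
  expect_s3_class(autoplot(fit), "ggplot")
})
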