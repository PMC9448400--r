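# small in-code fixtures shared across tests

# a tiny two-curve table
tiny_curves <- function() {
  tibble::tibble(
    sample_id = rep(c("A", "B"), each = 4),
    pH = rep(c(7.4, 7.4), each = 4),
    time_h = rep(c(1, 2, 4, 8), 2),
    released_pct = c(5, 9, 14, 22, 4, 7, 11, 18)
  )
}

# noiseless power-law curve: released_pct = 100 * k * t^n
power_law_curve <- function(k, n, times = c(1, 2, 4, 8, 16, 32, 64),
                            sample_id = "A", pH = 7.4) {
  tibble::tibble(sample_id = sample_id, pH = pH, time_h = times,
                 released_pct = 100 * k * times^n)
}

# noiseless saturating curve from the OU release law
ou_curve <- function(D, eta, times, sample_id = "A", pH = 7.4) {
  p <- mfrelease::ou_params(D = D, eta = eta)
  tibble::tibble(sample_id = sample_id, pH = pH, time_h = times,
                 released_pct = mfrelease::release_from_ou(times, p))
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
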