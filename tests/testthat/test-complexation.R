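test_that("binding_model solves the 1:1 equilibrium exactly", {
  expect_equal(binding_model(1e-3, 0, 4.5), 0)
  expect_lt(abs(binding_model(1e-3, 1e-3, 15) - 1e-3), 1e-8)
  # independent closed form: Kd = 10^-4.5, s = H0 + G0 + Kd
  kd <- 10^-4.5
  s <- 2e-3 + kd
  hg_ref <- (s - sqrt(s^2 - 4e-6)) / 2
  expect_equal(binding_model(1e-3, 1e-3, 4.5), hg_ref, tolerance = 1e-12)
  expect_equal(hg_ref, 8.373e-4, tolerance = 1e-4)
  expect_error(binding_model(-1e-3, 1e-3, 4.5), class = "argument_error")
  # monotone increasing in log_ka and bounded by the limiting reagent
  lks <- seq(1, 8, by = 0.5)
  hg <- binding_model(rep(2e-3, length(lks)), rep(0.5e-3, length(lks)), lks)
  expect_true(all(diff(hg) > 0))
  expect_true(all(hg <= 0.5e-3))
})

test_that("observed_shift is the population-weighted fast-exchange average", {
  expect_equal(observed_shift(1e-3, 0, 4.5, 3.85, 3.95), 3.85)
  expect_equal(observed_shift(1e-3, 1e-3, 15, 3.85, 3.95), 3.95, tolerance = 1e-6)
  expect_equal(observed_shift(1e-3, 1e-3, 4.5, 3.85, 3.95), 3.9337, tolerance = 1e-4)
  expect_error(observed_shift(0, 1e-3, 4.5, 3.85, 3.95), class = "argument_error")
})

test_that("the Job transform of a noiseless 1:1 series peaks at F = 0.5", {
  ser <- simulate_job_series(job_truth(), seq(0.1, 0.9, by = 0.05))
  jc <- job_transform(ser)
  expect_equal(unname(jc$argmax), rep(0.5, 6), tolerance = 1e-9)
  expect_equal(jc$argmax_pooled, 0.5, tolerance = 1e-9)
  # symmetry of the weighted response about F = 0.5
  for (j in seq_len(ncol(jc$y)))
    expect_lt(max(abs(jc$y[, j] - rev(jc$y[, j]))), 1e-9)
})

test_that("Job argmax is robust to shift noise at the experimental scale", {
  for (seed in 1:3) {
    ser <- simulate_job_series(job_truth(), seq(0.1, 0.9, by = 0.05),
                               noise_sd_ppm = 0.002, seed = seed)
    expect_lt(abs(job_transform(ser)$argmax_pooled - 0.5), 0.05)
  }
})

test_that("degenerate and underdetermined Job inputs are flagged or rejected", {
  flat <- titration_series(seq(0.1, 0.9, 0.1), matrix(3.85, 9, 1),
                           delta_free = 3.85)
  jc <- job_transform(flat)
  expect_true(all(jc$degenerate))
  expect_true(is.na(jc$argmax[1]))
  noanchor <- titration_series(seq(0.1, 0.9, 0.1), matrix(rnorm(9, 4), 9, 1))
  expect_error(job_transform(noanchor), class = "argument_error")
  narrow <- titration_series(seq(0.4, 0.6, 0.05), matrix(rnorm(5, 4), 5, 1),
                             delta_free = 3.85)
  expect_error(job_transform(narrow), class = "argument_error")
})

test_that("the simplex fit recovers a noiseless association constant exactly", {
  ser <- simulate_job_series(job_truth(), seq(0.1, 0.9, by = 0.1))
  fit <- fit_association_constant(ser)
  expect_true(fit$converged)
  expect_equal(fit$log_ka, 4.5, tolerance = 0.05)
  expect_lt(fit$rss, 1e-12)
  expect_equal(unname(fit$delta_bound), unname(job_truth()$delta_bound),
               tolerance = 1e-3)
})

test_that("fit recovery stays within the information limit across binding strengths", {
  fit_err <- function(lk, seeds) {
    vapply(seeds, function(i) {
      ser <- simulate_job_series(job_truth(lk), seq(0.1, 0.9, by = 0.1),
                                 noise_sd_ppm = 0.002, seed = i)
      abs(fit_association_constant(ser)$log_ka - lk)
    }, numeric(1))
  }
  expect_lt(median(fit_err(3.5, 1:20)), 0.1)
  expect_lt(median(fit_err(4.5, 1:20)), 0.1)
  # near-stoichiometric binding: Ka information lives only in the corner
  # rounding, so the attainable precision is lower
  expect_lt(median(fit_err(5.5, 1:20)), 0.2)
})

test_that("weak binding is recovered only to the product-degeneracy limit", {
  df <- c(H1 = 3.85, H2 = 4.0, H3 = 4.2, H4 = 4.4, H5 = 4.6, H6 = 4.8)
  errs <- vapply(1:20, function(i) {
    gt <- binding_ground_truth(2, delta_free = df, delta_bound = df + 1)
    ser <- simulate_job_series(gt, seq(0.1, 0.9, by = 0.1),
                               noise_sd_ppm = 0.002, seed = i)
    abs(fit_association_constant(ser)$log_ka - 2)
  }, numeric(1))
  expect_lt(median(errs), 0.3)
})

test_that("a series without shift variation raises a non-identifiability error", {
  flat <- titration_series(seq(0.1, 0.9, 0.1), matrix(3.85, 9, 2),
                           delta_free = c(3.85, 3.85))
  expect_error(fit_association_constant(flat), class = "non_identifiability_error")
  short <- titration_series(c(0.2, 0.5, 0.8), matrix(rnorm(3, 4), 3, 1),
                            delta_free = 3.85)
  expect_error(fit_association_constant(short), class = "argument_error")
})
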