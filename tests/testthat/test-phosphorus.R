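test_that("CSA is recovered from clean and noisy powder lineshapes", {
  m0 <- measure_csa(simulate_csa_powder(csa_model(58, broadening = 1)))
  expect_equal(m0$csa, 58, tolerance = 1)
  expect_false(m0$near_isotropic)
  expect_true(m0$perpendicular_peak <= m0$lowfield_edge + 1e-9 &&
                m0$perpendicular_peak >= m0$highfield_edge - 1e-9)
  vals <- vapply(1:10, function(i) {
    sp <- simulate_csa_powder(csa_model(40, broadening = 1), noise_sd = 0.005,
                              seed = i)
    measure_csa(sp)$csa
  }, numeric(1))
  expect_equal(mean(vals), 40, tolerance = 1)
})

test_that("the CSA estimate is monotone in the true anisotropy", {
  est <- vapply(c(10, 25, 40, 58, 80), function(c0)
    measure_csa(simulate_csa_powder(csa_model(c0, broadening = 1)))$csa, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - c(10, 25, 40, 58, 80)) < 1.5))
})

test_that("CSA measurement is invariant under axis translation and intensity scaling", {
  sp <- simulate_csa_powder(csa_model(58, broadening = 1), noise_sd = 0.01, seed = 2)
  m <- measure_csa(sp)
  moved <- sp; moved$axis <- sp$axis + 40; moved$intensity <- 7 * sp$intensity
  m2 <- measure_csa(moved)
  expect_equal(m2$csa, m$csa, tolerance = 1e-9)
  expect_equal(m2$lowfield_edge, m$lowfield_edge + 40, tolerance = 1e-9)
})

test_that("a single isotropic line is flagged near-isotropic and wrong units are rejected", {
  m <- measure_csa(simulate_csa_powder(csa_model(0, broadening = 1)))
  expect_true(m$near_isotropic)
  expect_lt(m$csa, 5)
  khz <- spectrum1d(seq(-10, 10, length.out = 64), rep(1, 64), unit = "kHz", mode = "2H")
  expect_error(measure_csa(khz), class = "unit_error")
})

test_that("isotropic components are classified by linewidth", {
  pure <- simulate_csa_powder(csa_model(58, broadening = 1), noise_sd = 0.01, seed = 4)
  d0 <- detect_isotropic(pure)
  expect_identical(d0$classification, "none")
  expect_lt(d0$area_fraction, 0.02)
  frag <- simulate_csa_powder(csa_model(58, broadening = 1,
    isotropic_components = list(list(position = 0, linewidth_hz = 600, amplitude = 0.3))),
    noise_sd = 0.01, seed = 5)
  df <- detect_isotropic(frag)
  expect_identical(df$classification, "fragments")
  expect_equal(df$linewidth_hz, 600, tolerance = 100)
  sol <- simulate_csa_powder(csa_model(58, broadening = 1,
    isotropic_components = list(list(position = 0, linewidth_hz = 30, amplitude = 0.2))),
    noise_sd = 0.01, seed = 6)
  ds <- detect_isotropic(sol)
  expect_identical(ds$classification, "solubilization")
})

test_that("isotropic area fractions are quantitative across the composition range", {
  for (f in c(0.1, 0.5, 0.9)) {
    sp <- simulate_csa_powder(csa_model(58, broadening = 1,
      isotropic_components = list(list(position = 0, linewidth_hz = 600, amplitude = f))),
      noise_sd = 0.005, seed = round(100 * f))
    expect_lt(abs(detect_isotropic(sp)$area_fraction - f), 0.05)
  }
})

test_that("the logistic transition fit recovers clean and noisy midpoints", {
  gt <- transition_ground_truth(76, 58, 297, 0.8)
  clean <- fit_transition(simulate_transition_series(gt, 290:310))
  expect_true(clean$converged)
  expect_equal(clean$midpoint, 297, tolerance = 0.1)
  expect_equal(clean$low_value, 76, tolerance = 0.5)
  expect_equal(clean$high_value, 58, tolerance = 0.5)
  # shifted transition with 2% relative noise
  mids <- vapply(1:10, function(i) {
    ser <- simulate_transition_series(transition_ground_truth(76, 58, 296, 0.8),
                                      290:310, noise_sd = 0.02,
                                      noise_type = "relative", seed = i)
    fit_transition(ser)$midpoint
  }, numeric(1))
  expect_true(all(abs(mids - 296) < 0.5))
})

test_that("flat series yield a no-transition flag, short series an error", {
  flat <- data.frame(T_K = 290:310, v = 67 + sin(290:310) * 0.05)
  f <- fit_transition(flat)
  expect_true(f$no_transition)
  expect_false(f$converged)
  expect_error(fit_transition(data.frame(T_K = 1:5, v = rnorm(5))),
               class = "argument_error")
})
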