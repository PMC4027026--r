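test_that("a single Pake doublet has horns at the 90-degree splitting and shoulders at twice it", {
  sp <- simulate_pake_spectrum(pake_component(4, 1, "CD3"), broadening_khz = 0.05,
                               axis_range_khz = 10, n_points = 4096)
  y <- sp$intensity
  horns <- which(diff(sign(diff(y))) == -2) + 1L
  horns <- horns[y[horns] > 0.5 * max(y)]
  expect_length(horns, 2L)
  expect_equal(diff(sp$axis[horns]), 4, tolerance = 0.05)
  # outermost signal (0-degree shoulders) reaches +/- the full splitting
  # and no further than that plus broadening tails
  outer <- range(sp$axis[y > 0.005 * max(y)])
  expect_gt(outer[2], 3.9)
  expect_lt(outer[2], 4.6)
})

test_that("noiseless powder spectra are symmetric and zero components give a flat baseline", {
  sp <- simulate_pake_spectrum(pake_component(c(4, 12, 29), c(6, 4, 28)),
                               broadening_khz = 0.5, axis_range_khz = 35)
  expect_lt(max(abs(sp$intensity - rev(sp$intensity))) / max(sp$intensity), 1e-6)
  flat <- simulate_pake_spectrum(pake_component(numeric(0)), axis_range_khz = 10)
  expect_true(all(flat$intensity == 0))
})

test_that("powder intensity is linear in the component weights before normalization", {
  one <- simulate_pake_spectrum(pake_component(10, 2), broadening_khz = 0.4,
                                axis_range_khz = 15, normalize = FALSE)
  three <- simulate_pake_spectrum(pake_component(10, 6), broadening_khz = 0.4,
                                  axis_range_khz = 15, normalize = FALSE)
  expect_equal(three$intensity, 3 * one$intensity, tolerance = 1e-6)
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_pake_spectrum(pake_component(10, 1), noise_sd = 0.05, seed = 3)
  b <- simulate_pake_spectrum(pake_component(10, 1), noise_sd = 0.05, seed = 3)
  expect_identical(a$intensity, b$intensity)
  e1 <- simulate_esr_spectrum(esr_model(60, 20), noise_sd = 0.02, seed = 9)
  e2 <- simulate_esr_spectrum(esr_model(60, 20), noise_sd = 0.02, seed = 9)
  expect_identical(e1$intensity, e2$intensity)
  t1 <- simulate_transition_series(transition_ground_truth(76, 58, 297, 0.8),
                                   290:310, noise_sd = 0.5, seed = 4)
  t2 <- simulate_transition_series(transition_ground_truth(76, 58, 297, 0.8),
                                   290:310, noise_sd = 0.5, seed = 4)
  expect_identical(t1, t2)
})

test_that("an overly narrow axis or a negative broadening is rejected", {
  expect_error(simulate_pake_spectrum(pake_component(30, 1), axis_range_khz = 20),
               class = "range_error")
  expect_error(simulate_pake_spectrum(pake_component(5, 1), broadening_khz = -1),
               class = "argument_error")
})

test_that("the DMPC-d54 fixtures carry the published endpoint splittings", {
  f <- dmpc_d54_fixture("DMPC", 298)
  expect_equal(f$splitting_90[f$label == "CD3"], 4.0)
  expect_equal(f$splitting_90[f$label == "plateau"], 29.0)
  expect_equal(f$weight[f$label == "CD3"], 6)
  expect_equal(f$weight[f$label == "plateau"], 28)
  expect_equal(nrow(f), 8L)
  expect_true(all(diff(f$splitting_90) > 0))
  expect_equal(dmpc_d54_fixture("DMPC+CYSP", 298)$splitting_90[8], 31.0)
  expect_equal(dmpc_d54_fixture("DMPC+POLYA", 298)$splitting_90[1], 3.6)
  expect_equal(dmpc_d54_fixture("DMPC+ASD", 298)$splitting_90[1], 4.4)
  expect_error(dmpc_d54_fixture("DMPC", 300), class = "argument_error")
})

test_that("the CSA powder generator places its edges exactly one CSA apart", {
  sp <- simulate_csa_powder(csa_model(58, broadening = 0.3))
  y <- sp$intensity
  lo <- min(sp$axis[y > 0.02]); hi <- max(sp$axis[y > 0.02])
  expect_equal(hi - lo, 58, tolerance = 1.5)
  expect_equal(sp$axis[which.max(y)], 58 / 3, tolerance = 0.5)
  single <- simulate_csa_powder(csa_model(0, iso_position = -3, broadening = 1))
  expect_equal(single$axis[which.max(single$intensity)], -3, tolerance = 0.1)
})

test_that("an added isotropic line is visible at the isotropic position", {
  plain <- simulate_csa_powder(csa_model(58, broadening = 1))
  with_line <- simulate_csa_powder(csa_model(58, broadening = 1,
    isotropic_components = list(list(position = 0, linewidth_hz = 600, amplitude = 0.3))))
  at0 <- function(s) s$intensity[which.min(abs(s$axis))]
  expect_gt(at0(with_line) / max(with_line$intensity),
            2 * at0(plain) / max(plain$intensity))
})

test_that("ESR derivative extrema sit at the requested hyperfine separations", {
  sp <- simulate_esr_spectrum(esr_model(60, 20, center = 3350, linewidth = 1.5))
  y <- sp$intensity; x <- sp$axis
  expect_equal(x[which.max(y)] , 3350 - 30, tolerance = 0.5)
  expect_equal(x[which.min(y)], 3350 + 30, tolerance = 0.5)
  expect_error(esr_model(20, 60), class = "argument_error")
  expect_warning(simulate_esr_spectrum(esr_model(30.2, 30, linewidth = 1.5)),
                 "overlap")
})

test_that("the logistic series passes through the midpoint value and its asymptotes", {
  gt <- transition_ground_truth(76, 58, 297, 0.8)
  ser <- simulate_transition_series(gt, c(260, 290:304, 340))
  expect_equal(ser[[2]][ser$T_K == 297], 67.0)
  expect_equal(ser[[2]][ser$T_K == 340], 58, tolerance = 1e-6)
  expect_equal(ser[[2]][ser$T_K == 260], 76, tolerance = 1e-6)
  expect_true(all(diff(ser[[2]]) < 0))
  expect_error(simulate_transition_series(gt, numeric(0)), class = "argument_error")
})

test_that("the Job-series generator follows the exact 1:1 fast-exchange shifts", {
  gt <- binding_ground_truth(4.5, delta_free = c(H = 3.85), delta_bound = c(H = 3.95))
  ser <- simulate_job_series(gt, c(0.25, 0.5, 0.75))
  # closed form at F = 0.5: H0 = G0 = 1 mM, Kd = 10^-4.5 M
  kd <- 10^-4.5
  hg <- (2e-3 + kd - sqrt((2e-3 + kd)^2 - 4e-6)) / 2
  expect_equal(hg / 1e-3, 0.837, tolerance = 5e-4)
  expect_equal(unname(ser$shifts[2, "H"]), 3.85 + 0.1 * hg / 1e-3, tolerance = 1e-12)
  # saturation: enormous Ka drives the F = 0.5 shift to the bound limit
  sat <- simulate_job_series(binding_ground_truth(12, c(H = 3.85), c(H = 3.95)), 0.5)
  expect_equal(unname(sat$shifts[1, "H"]), 3.95, tolerance = 1e-6)
  same <- simulate_job_series(binding_ground_truth(4.5, c(H = 3.85), c(H = 3.85)),
                              c(0.3, 0.5, 0.7))
  expect_true(all(same$shifts == 3.85))
  expect_error(simulate_job_series(gt, c(0, 0.5)), class = "argument_error")
})
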