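test_that("the orientation-angle order parameter matches its closed form and bounds", {
  expect_equal(scd_from_angle(0), 1)
  expect_equal(scd_from_angle(90), -0.5)
  expect_equal(scd_from_angle(54.7356), 0, tolerance = 1e-6)
  beta <- seq(-720, 720, by = 0.5)
  s <- scd_from_angle(beta)
  expect_true(all(s >= -0.5 - 1e-12 & s <= 1 + 1e-12))
})

test_that("order parameters scale linearly with the quadrupolar splitting", {
  expect_equal(order_parameter_from_splitting(0), 0)
  expect_equal(order_parameter_from_splitting(29), 0.22745, tolerance = 1e-4)
  expect_equal(order_parameter_from_splitting(4), 0.03137, tolerance = 1e-4)
  d <- seq(0, 35, by = 0.5)
  expect_equal(order_parameter_from_splitting(d), d / 127.5)
  expect_error(order_parameter_from_splitting(-1), class = "argument_error")
  expect_warning(order_parameter_from_splitting(200), "exceeds 1")
})

test_that("symmetrize returns the even part and records the asymmetry", {
  sp <- simulate_pake_spectrum(pake_component(10, 1), broadening_khz = 0.5,
                               axis_range_khz = 15)
  sym <- symmetrize(sp, 0)
  expect_equal(sym$intensity, sp$intensity, tolerance = 1e-9)
  expect_lt(sym$metadata$asymmetry_fraction, 1e-6)
  # a purely odd perturbation is removed entirely
  odd <- sp
  odd$intensity <- sp$intensity + 0.2 * sin(sp$axis)
  fixed <- symmetrize(odd, 0)
  expect_equal(fixed$intensity, sp$intensity, tolerance = 1e-9)
  expect_error(symmetrize(sp, 99), class = "argument_error")
})

test_that("de-Pake-ing inverts a single broadened doublet", {
  sp <- simulate_pake_spectrum(pake_component(10, 1), broadening_khz = 0.5,
                               axis_range_khz = 15, n_points = 1024)
  d <- depake(sp, grid = seq(0.5, 14, by = 0.1), lambda = 0)
  expect_lt(d$residual, 1e-3)
  ex <- extract_splittings(d)
  expect_equal(ex$delta_nu_q[which.max(ex$weight)], 10, tolerance = 0.1)
  expect_true(all(d$weights >= 0))
})

test_that("de-Pake input validation catches degenerate and out-of-range cases", {
  sp <- simulate_pake_spectrum(pake_component(10, 1), axis_range_khz = 15,
                               n_points = 512)
  expect_error(depake(sp, grid = seq(1, 30, 0.5)), class = "range_error")
  zero <- spectrum1d(seq(-10, 10, length.out = 64), rep(0, 64),
                     unit = "kHz", mode = "2H")
  expect_error(depake(zero), class = "degenerate_input_error")
})

test_that("extraction merges peaks inside the separation radius and flags empty results", {
  d <- structure(list(grid = seq(1, 30, by = 0.1),
                      weights = rep(0, 291), lambda = 0, residual = 0,
                      broadening_khz = 0.5), class = "splitting_distribution")
  d$weights[c(91, 96)] <- c(2, 1)   # peaks at 10.0 and 10.5 kHz
  ex <- extract_splittings(d, min_separation_khz = 1)
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$delta_nu_q, (10 * 2 + 10.5 * 1) / 3, tolerance = 1e-6)
  expect_equal(ex$weight, 3)
  d$weights[] <- 0
  expect_warning(ex0 <- extract_splittings(d), "no splitting")
  expect_true(attr(ex0, "empty"))
})

test_that("profiles assign CD3, intermediate carbons, and the plateau by splitting order", {
  p <- assign_profile(c(29, 4), system = "DMPC", temperature = 298)
  expect_equal(p$profile$label, c("CD3", "plateau"))
  expect_equal(p$profile$delta_nu_q, c(4, 29))
  expect_equal(p$profile$s_cd, c(4, 29) / 127.5)
  full <- assign_profile(c(4, 7.6, 11.1, 14.7, 18.3, 21.9, 25.4, 29))
  expect_equal(full$profile$label,
               c("CD3", "C14", "C13", "C12", "C11", "C10", "C9", "plateau"))
  expect_error(assign_profile(4), class = "assignment_error")
})

test_that("relative fluidity reproduces the reference comparisons", {
  ref <- assign_profile(c(4, 29), system = "DMPC")
  polya <- assign_profile(c(3.6, 26.6), system = "DMPC+POLYA")
  asd <- assign_profile(c(4.4, 28.0), system = "DMPC+ASD")
  r_p <- relative_fluidity(polya, ref)$table
  expect_equal(r_p$R[r_p$label == "plateau"], (26.6 - 29) / 29, tolerance = 1e-9)
  r_a <- relative_fluidity(asd, ref)$table
  expect_equal(r_a$R[r_a$label == "CD3"], 0.10, tolerance = 1e-9)
  expect_true(all(relative_fluidity(ref, ref)$table$R == 0))
  other <- assign_profile(c(3, 12, 28))
  expect_error(relative_fluidity(other, ref), class = "alignment_error")
})

test_that("de-Pake round-trips recover random chain profiles without spurious components", {
  set.seed(123)
  grid_step <- 0.25
  tol <- max(0.5, grid_step)
  for (i in 1:20) {
    cmp <- random_components()
    sp <- simulate_pake_spectrum(pake_component(cmp$splittings, cmp$weights),
                                 broadening_khz = cmp$broadening,
                                 axis_range_khz = 40, n_points = 1024,
                                 noise_sd = 0.015, n_orientations = 1000, seed = i)
    d <- depake(sp, grid = seq(0.5, 38, by = grid_step), lambda = "auto",
                broadening_khz = cmp$broadening, n_orientations = 1000)
    ex <- extract_splittings(d, min_separation_khz = 1.5)
    for (tv in cmp$splittings)
      expect_lt(min(abs(ex$delta_nu_q - tv)), tol)
    spurious <- ex$weight > 0.1 * max(ex$weight) &
      vapply(ex$delta_nu_q, function(p) min(abs(p - cmp$splittings)) > tol, logical(1))
    expect_false(any(spurious))
  }
})
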