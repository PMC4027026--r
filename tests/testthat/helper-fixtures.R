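# Shared ground truths and generator shortcuts for the test suite.

# Six host resonances at the free shifts of the cyclodextrin glucose protons,
# with bound-shift perturbations of 0.06-0.12 ppm.
job_truth <- function(log_ka = 4.5) {
  df <- c(H1 = 5.29, H2 = 3.85, H3 = 4.43, H4 = 4.27, H5 = 4.05, H6 = 4.30)
  binding_ground_truth(log_ka, delta_free = df,
                       delta_bound = df + c(0.10, 0.06, 0.12, 0.08, 0.09, 0.07))
}

# DMPC-d54 fixture spectrum at the default analysis conditions.
fixture_spectrum <- function(system, seed = 7, noise_sd = 0.01,
                             n_points = 2048, temperature = 298) {
  simulate_pake_spectrum(dmpc_d54_fixture(system, temperature),
                         broadening_khz = 0.5, axis_range_khz = 40,
                         n_points = n_points, noise_sd = noise_sd, seed = seed)
}

depake_fixture <- function(sp) {
  depake(sp, grid = seq(0.5, 36, by = 0.1), lambda = "auto", broadening_khz = 0.5)
}

# Random multi-component chain profile for the round-trip property tests.
# Components must be mutually resolvable: separations at least three
# Lorentzian linewidths (and 2.5 kHz), the inversion's resolution limit at
# these signal-to-noise ratios.
random_components <- function() {
  k <- sample(2:9, 1)
  broadening <- runif(1, 0.2, 1)
  min_gap <- max(2.5, 3 * broadening)
  repeat {
    tr <- sort(runif(k, 2, 35))
    if (k == 1 || min(diff(tr)) > min_gap) break
  }
  list(splittings = tr, weights = runif(k, 1, 5), broadening = broadening)
}
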