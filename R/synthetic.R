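# Synthetic-spectrum generators. Every analysis stage in the package is
# validated against these: each generator has explicit ground truth and an
# explicit seed, so analysis round-trips are testable.

#' Pake doublet components
#'
#' A component is one C-D position of a perdeuterated acyl chain: its 90
#' degree (horn) quadrupolar splitting, a weight proportional to the number
#' of equivalent deuterons, and a chain-position label.
#'
#' @param splitting_90 quadrupolar splitting at the 90 degree orientation,
#'   kHz, >= 0.
#' @param weight relative deuteron count, >= 0.
#' @param label chain-position tag (e.g. `"CD3"`, `"C9"`, `"plateau"`).
#' @return data.frame with one row per component.
#' @export
pake_component <- function(splitting_90, weight = 1, label = NA_character_) {
  if (any(splitting_90 < 0)) .stop_class("splitting_90 must be >= 0", "argument_error")
  if (any(weight < 0)) .stop_class("weight must be >= 0", "argument_error")
  data.frame(splitting_90 = as.numeric(splitting_90),
             weight = as.numeric(rep_len(weight, length(splitting_90))),
             label = rep_len(as.character(label), length(splitting_90)),
             stringsAsFactors = FALSE)
}

#' Simulate a superposition of Pake doublets (2H powder spectrum)
#'
#' For each component the powder average is computed on a uniform cos(theta)
#' orientation grid: a deuteron at orientation theta resonates at
#' nu = +/- splitting_90 * (3 cos^2 theta - 1)/2, so the 90 degree horns are
#' separated by `splitting_90` and the 0 degree shoulders by twice that. The
#' binned orientation histogram is convolved with a Lorentzian of FWHM
#' `broadening_khz`, components are summed with their weights, the spectrum
#' is normalized to unit maximum, and seeded Gaussian noise is added last
#' (the noiseless spectrum is symmetric about zero).
#'
#' @param components data.frame from [pake_component()] (zero rows allowed:
#'   flat baseline).
#' @param broadening_khz Lorentzian FWHM, kHz.
#' @param axis_range_khz half-range of the symmetric axis; must cover the
#'   largest 0 degree shoulder (i.e. be >= the largest splitting).
#' @param n_points number of axis points (>= 256).
#' @param noise_sd Gaussian noise s.d. in units of the normalized maximum
#'   (e.g. 0.01 is a signal-to-noise ratio of 100).
#' @param n_orientations orientation grid size (>= 2000 by default).
#' @param isotropic_components optional list of `list(position, linewidth_khz,
#'   amplitude)` isotropic Lorentzian lines; `amplitude` is the fraction of
#'   the total integrated area carried by the line (degraded-membrane
#'   spectra combine residual doublets with such a line).
#' @param normalize rescale to unit maximum (default); with `FALSE` the
#'   integrated intensity stays proportional to the summed weights.
#' @param seed integer RNG seed for the noise, or `NULL`.
#' @return A [spectrum1d()] (kHz, mode `"2H"`); ground truth is stored in
#'   `metadata$ground_truth`.
#' @export
simulate_pake_spectrum <- function(components, broadening_khz = 0.5,
                                   axis_range_khz = NULL, n_points = 2048,
                                   noise_sd = 0, n_orientations = 2000,
                                   isotropic_components = list(),
                                   normalize = TRUE, seed = NULL) {
  if (broadening_khz < 0) .stop_class("broadening_khz must be >= 0", "argument_error")
  if (n_points < 256) .stop_class("n_points must be >= 256", "argument_error")
  if (is.null(components) || nrow(components) == 0L)
    components <- pake_component(numeric(0), numeric(0))
  dmax <- if (nrow(components)) max(components$splitting_90) else 0
  if (is.null(axis_range_khz))
    axis_range_khz <- max(1.25 * dmax + 6 * broadening_khz, 10)
  if (dmax > 0 && axis_range_khz < dmax)
    .stop_class(sprintf(
      "axis_range_khz = %g too narrow: 0-degree shoulders extend to +/- %g kHz",
      axis_range_khz, dmax), "range_error")
  axis <- seq(-axis_range_khz, axis_range_khz, length.out = n_points)
  u <- (seq_len(n_orientations) - 0.5) / n_orientations
  orient <- (3 * u^2 - 1) / 2
  y <- numeric(n_points)
  for (i in seq_len(nrow(components))) {
    nu <- components$splitting_90[i] * orient
    y <- y + .bin_deltas(axis, c(nu, -nu),
                         rep(components$weight[i] / (2 * n_orientations),
                             2 * n_orientations))
  }
  y <- .lorentz_conv(axis, y, broadening_khz)
  y <- .add_isotropic_lines(axis, y, isotropic_components)
  if (normalize && max(y) > 0) y <- y / max(y)
  y <- .add_noise(y, noise_sd, seed)
  spectrum1d(axis, y, unit = "kHz", mode = "2H",
             metadata = list(ground_truth = list(
               components = components, broadening_khz = broadening_khz,
               isotropic_components = isotropic_components,
               noise_sd = noise_sd, seed = seed)))
}

.add_noise <- function(y, noise_sd, seed) {
  if (noise_sd > 0) y <- y + .with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  y
}

# Add isotropic Lorentzian lines specified as area fractions of the total.
.add_isotropic_lines <- function(axis, y, comps, unit_scale = 1) {
  if (length(comps) == 0L) return(y)
  base_area <- .trapz(axis, y)
  fr <- vapply(comps, function(cc) cc$amplitude, numeric(1))
  if (any(fr < 0) || sum(fr) >= 1)
    .stop_class("isotropic line area fractions must be in [0, 1) and sum below 1",
                "argument_error")
  if (base_area <= 0) base_area <- 1   # pure-isotropic spectrum
  total <- base_area / (1 - sum(fr))
  for (cc in comps) {
    g <- cc[[2]] * unit_scale / 2      # linewidth given as FWHM
    if (g <= 0) .stop_class("isotropic linewidth must be > 0", "argument_error")
    prof <- .lorentz_profile(axis, cc$position, g)
    y <- y + prof * (cc$amplitude * total) / (pi * g)
  }
  y
}

#' Canonical DMPC-d54 acyl-chain splitting fixtures
#'
#' Component lists for chain-perdeuterated DMPC multilamellar dispersions,
#' pure or carrying cyclosporin A (CYSP), the poly-alpha-cyclodextrin
#' copolymer (POLYA), or their amorphous solid dispersion (ASD). At 298 K the
#' CD3 and plateau (C2-C8) endpoint splittings are the measured literature
#' values for these systems; the six intermediate C14..C9 positions are not
#' reported individually and default to linear interpolation between the
#' endpoints (the profile is monotone). Weights count deuterons over both
#' chains: CD3 = 6, each resolved CD2 = 4, plateau (7 positions) = 28.
#'
#' The 308 K lists are synthetic stand-ins: no per-position values are
#' published at that temperature, so the endpoints are scaled versions of the
#' 298 K values consistent with the qualitative picture (global fluidization
#' on warming; CYSP effects nearly vanished; POLYA fluidization more
#' pronounced; ASD mildly rigidifying).
#'
#' @param system `"DMPC"`, `"DMPC+CYSP"`, `"DMPC+POLYA"` or `"DMPC+ASD"`.
#' @param temperature 298 or 308 (K).
#' @param interpolation optional function(cd3, plateau) returning the six
#'   intermediate splittings C14..C9 (ascending); default linear.
#' @return data.frame of [pake_component()] rows, CD3 first.
#' @export
dmpc_d54_fixture <- function(system = c("DMPC", "DMPC+CYSP", "DMPC+POLYA", "DMPC+ASD"),
                             temperature = 298, interpolation = NULL) {
  system <- match.arg(system)
  if (!temperature %in% c(298, 308))
    .stop_class("temperature must be 298 or 308 K", "argument_error")
  ends <- list(
    `298` = list("DMPC" = c(4.0, 29.0), "DMPC+CYSP" = c(4.2, 31.0),
                 "DMPC+POLYA" = c(3.6, 26.6), "DMPC+ASD" = c(4.4, 28.0)),
    # synthetic stand-ins, see above
    `308` = list("DMPC" = c(3.5, 25.5), "DMPC+CYSP" = c(3.5, 25.7),
                 "DMPC+POLYA" = c(3.1, 23.0), "DMPC+ASD" = c(3.7, 26.6)))
  e <- ends[[as.character(temperature)]][[system]]
  cd3 <- e[1]; plateau <- e[2]
  mids <- if (is.null(interpolation)) seq(cd3, plateau, length.out = 8)[2:7]
          else interpolation(cd3, plateau)
  rbind(pake_component(cd3, 6, "CD3"),
        pake_component(mids, 4, paste0("C", 14:9)),
        pake_component(plateau, 28, "plateau"))
}

#' Axially symmetric CSA lineshape model
#'
#' @param csa chemical shift anisotropy (lowfield minus highfield edge), ppm,
#'   >= 0.
#' @param iso_position isotropic shift, ppm.
#' @param broadening Lorentzian FWHM, ppm.
#' @param isotropic_components list of `list(position, linewidth_hz,
#'   amplitude)`; `amplitude` is the area fraction of the total spectrum.
#' @param reference_frequency operating frequency in MHz, used to convert the
#'   isotropic linewidths from Hz to ppm.
#' @export
csa_model <- function(csa, iso_position = 0, broadening = 1,
                      isotropic_components = list(), reference_frequency = 162) {
  if (csa < 0) .stop_class("csa must be >= 0", "argument_error")
  if (broadening <= 0) .stop_class("broadening must be > 0", "argument_error")
  structure(list(csa = csa, iso_position = iso_position, broadening = broadening,
                 isotropic_components = isotropic_components,
                 reference_frequency = reference_frequency),
            class = "csa_model")
}

#' Simulate an axially symmetric 31P powder lineshape
#'
#' The shift tensor is averaged over a uniform cos(theta) orientation grid:
#' sigma(theta) = sigma_perp + (sigma_par - sigma_perp) cos^2(theta) with the
#' perpendicular edge at `iso_position + csa/3` (the intensity maximum, at
#' low field for the motionally averaged phospholipid tensor) and the
#' parallel edge at `iso_position - 2 csa/3`, so the edge separation is
#' exactly `csa`. Isotropic Lorentzian components are then added, the
#' spectrum is normalized to unit maximum, and seeded noise applied.
#'
#' @param model a [csa_model()].
#' @param n_points axis points.
#' @param noise_sd Gaussian noise s.d. relative to unit maximum.
#' @param n_orientations orientation grid size.
#' @param seed RNG seed or `NULL`.
#' @return A [spectrum1d()] (ppm, mode `"31P"`).
#' @export
simulate_csa_powder <- function(model, n_points = 2048, noise_sd = 0,
                                n_orientations = 2000, seed = NULL) {
  stopifnot(inherits(model, "csa_model"))
  iso <- model$iso_position
  s_perp <- iso + model$csa / 3
  s_par <- iso - 2 * model$csa / 3
  pad <- max(8 * model$broadening, 0.2 * model$csa, 5)
  axis <- seq(s_par - pad, s_perp + pad, length.out = n_points)
  u <- (seq_len(n_orientations) - 0.5) / n_orientations
  y <- .bin_deltas(axis, s_perp + (s_par - s_perp) * u^2,
                   rep(1 / n_orientations, n_orientations))
  y <- .lorentz_conv(axis, y, model$broadening)
  iso_ppm <- lapply(model$isotropic_components, function(cc)
    list(position = cc$position, linewidth = cc$linewidth_hz / model$reference_frequency,
         amplitude = cc$amplitude))
  y <- .add_isotropic_lines(axis, y, iso_ppm)
  if (max(y) > 0) y <- y / max(y)
  y <- .add_noise(y, noise_sd, seed)
  spectrum1d(axis, y, unit = "ppm", mode = "31P",
             metadata = list(ground_truth = list(
               csa = model$csa, iso_position = iso, broadening = model$broadening,
               isotropic_components = model$isotropic_components,
               reference_frequency = model$reference_frequency,
               noise_sd = noise_sd, seed = seed)))
}

#' Nitroxide ESR lineshape model
#'
#' @param two_T_par outer hyperfine extrema separation 2T-parallel, Gauss.
#' @param two_T_perp inner hyperfine extrema separation 2T-perpendicular,
#'   Gauss; must satisfy `two_T_par > two_T_perp > 0`.
#' @param center field center, Gauss.
#' @param linewidth component linewidth, Gauss.
#' @export
esr_model <- function(two_T_par, two_T_perp, center = 3350, linewidth = 1.5) {
  if (!(two_T_par > two_T_perp && two_T_perp > 0))
    .stop_class("need two_T_par > two_T_perp > 0", "argument_error")
  if (linewidth <= 0) .stop_class("linewidth must be > 0", "argument_error")
  structure(list(two_T_par = two_T_par, two_T_perp = two_T_perp,
                 center = center, linewidth = linewidth), class = "esr_model")
}

#' Simulate a first-derivative nitroxide ESR spectrum
#'
#' A phenomenological construction constrained by the two measurable
#' splittings (a full slow-motion simulation is out of scope): the derivative
#' trace is a central first-derivative line plus two pairs of Gaussian
#' features placed so that the outermost maximum/minimum are separated by
#' exactly `two_T_par` (positive wing at low field, negative at high field)
#' and the flanking inner extrema pair (low-field minimum, high-field
#' maximum) by exactly `two_T_perp` -- the geometry of a membrane-embedded
#' 5-DOXYL stearate spectrum.
#'
#' @param model an [esr_model()].
#' @param n_points axis points.
#' @param noise_sd Gaussian noise s.d. relative to unit maximum amplitude.
#' @param seed RNG seed or `NULL`.
#' @return A [spectrum1d()] (Gauss, mode `"ESR-derivative"`).
#' @export
simulate_esr_spectrum <- function(model, n_points = 2048, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "esr_model"))
  c0 <- model$center
  tpar <- model$two_T_par / 2
  tperp <- model$two_T_perp / 2
  w <- model$linewidth
  if ((tpar - tperp) < 3 * w)
    warning("hyperfine separations within ~3 linewidths; extrema may overlap")
  half <- tpar + 12 * w
  x <- seq(c0 - half, c0 + half, length.out = n_points)
  nd <- function(z, wid) (z / wid) * exp(0.5 - z^2 / (2 * wid^2))  # unit extrema at +/- wid
  g <- function(z, wid) exp(-z^2 / (2 * wid^2))
  y <- -nd(x - c0, w) +
    0.45 * (-g(x - (c0 - tperp), w) + g(x - (c0 + tperp), w)) +
    0.30 * (g(x - (c0 - tpar), 1.6 * w) - g(x - (c0 + tpar), 1.6 * w))
  y <- y / max(abs(y))
  y <- .add_noise(y, noise_sd, seed)
  spectrum1d(x, y, unit = "Gauss", mode = "ESR-derivative",
             metadata = list(ground_truth = list(
               two_T_par = model$two_T_par, two_T_perp = model$two_T_perp,
               center = c0, linewidth = w, noise_sd = noise_sd, seed = seed)))
}

#' Transition ground truth and sigmoidal temperature series
#'
#' `simulate_transition_series()` evaluates
#' `obs(T) = high + (low - high) * plogis((midpoint - T)/width)` so the
#' observable equals `low_T_value` far below the transition, `high_T_value`
#' far above it, and their midpoint at `T = midpoint` (monotone decreasing
#' in T when `low_T_value > high_T_value`, as for CSA or order parameters).
#'
#' @param low_T_value,high_T_value asymptotic observable values below/above
#'   the transition.
#' @param midpoint transition midpoint, K.
#' @param width transition width, K, > 0.
#' @export
transition_ground_truth <- function(low_T_value, high_T_value, midpoint, width) {
  if (width <= 0) .stop_class("width must be > 0", "argument_error")
  structure(list(low_T_value = low_T_value, high_T_value = high_T_value,
                 midpoint = midpoint, width = width), class = "transition_ground_truth")
}

#' @rdname transition_ground_truth
#' @param gt a [transition_ground_truth()].
#' @param temperatures temperatures in K (>= 6, spanning the midpoint, for
#'   downstream fitting).
#' @param noise_sd noise s.d.; absolute, or relative to the local value when
#'   `noise_type = "relative"`.
#' @param noise_type `"absolute"` or `"relative"`.
#' @param observable observable column name for the output table.
#' @param seed RNG seed or `NULL`.
#' @return data.frame with columns `T_K` and `observable`.
#' @export
simulate_transition_series <- function(gt, temperatures, noise_sd = 0,
                                       noise_type = c("absolute", "relative"),
                                       observable = "value", seed = NULL) {
  stopifnot(inherits(gt, "transition_ground_truth"))
  noise_type <- match.arg(noise_type)
  if (length(temperatures) == 0L)
    .stop_class("temperatures must be non-empty", "argument_error")
  temperatures <- sort(as.numeric(temperatures))
  y <- gt$high_T_value + (gt$low_T_value - gt$high_T_value) *
    stats::plogis((gt$midpoint - temperatures) / gt$width)
  if (noise_sd > 0) {
    sdv <- if (noise_type == "relative") noise_sd * abs(y) else rep(noise_sd, length(y))
    y <- y + .with_seed(seed, stats::rnorm(length(y), sd = sdv))
  }
  out <- data.frame(T_K = temperatures, y)
  names(out)[2] <- observable
  out
}

#' Ground truth for a fast-exchange 1:1 binding series
#'
#' @param log_ka log10 of the apparent association constant, M^-1.
#' @param delta_free,delta_bound free and fully bound host chemical shifts,
#'   ppm; vectors (one entry per observed resonance), optionally named.
#' @param total_conc total concentration held fixed across the series, M
#'   (continuous-variations design; 2 mM default).
#' @param stoichiometry host:guest integers; only `c(1, 1)` is supported.
#' @export
binding_ground_truth <- function(log_ka, delta_free, delta_bound,
                                 total_conc = 2e-3, stoichiometry = c(1, 1)) {
  if (!is.finite(log_ka)) .stop_class("log_ka must be finite", "argument_error")
  if (total_conc <= 0) .stop_class("total_conc must be > 0", "argument_error")
  if (!identical(as.integer(stoichiometry), c(1L, 1L)))
    .stop_class("only 1:1 stoichiometry is supported", "argument_error")
  if (length(delta_free) != length(delta_bound))
    .stop_class("delta_free and delta_bound must have equal length", "argument_error")
  labels <- names(delta_free)
  if (is.null(labels)) labels <- paste0("res", seq_along(delta_free))
  structure(list(log_ka = log_ka, delta_free = stats::setNames(delta_free, labels),
                 delta_bound = stats::setNames(delta_bound, labels),
                 total_conc = total_conc, stoichiometry = c(1L, 1L)),
            class = "binding_ground_truth")
}

#' Simulate a continuous-variations (Job) titration series
#'
#' At host molar fraction F the initial concentrations are `H0 = F * total`
#' and `G0 = (1 - F) * total`; the complex concentration follows the exact
#' 1:1 equilibrium ([binding_model()]) and the observed host shift is the
#' fast-exchange population average
#' `delta_free + (delta_bound - delta_free) * [HG]/H0`.
#'
#' @param gt a [binding_ground_truth()].
#' @param fractions host molar fractions, strictly inside (0, 1).
#' @param noise_sd_ppm Gaussian shift noise s.d., ppm.
#' @param seed RNG seed or `NULL`.
#' @return A `titration_series` object (see [titration_series()]).
#' @export
simulate_job_series <- function(gt, fractions, noise_sd_ppm = 0, seed = NULL) {
  stopifnot(inherits(gt, "binding_ground_truth"))
  if (any(fractions <= 0 | fractions >= 1))
    .stop_class("fractions must lie strictly inside (0, 1)", "argument_error")
  fractions <- sort(fractions)
  H0 <- fractions * gt$total_conc
  G0 <- (1 - fractions) * gt$total_conc
  b <- binding_model(H0, G0, gt$log_ka) / H0
  shifts <- outer(b, gt$delta_bound - gt$delta_free) +
    matrix(gt$delta_free, length(b), length(gt$delta_free), byrow = TRUE)
  if (noise_sd_ppm > 0)
    shifts <- shifts + .with_seed(seed, matrix(stats::rnorm(length(shifts),
                                                            sd = noise_sd_ppm),
                                               nrow(shifts)))
  colnames(shifts) <- names(gt$delta_free)
  titration_series(fractions, shifts, total_conc = gt$total_conc,
                   delta_free = gt$delta_free)
}
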