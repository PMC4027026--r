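# Nitroxide spin-label ESR analysis: hyperfine splittings from
# first-derivative spectra and the apparent order parameter.

#' Measure hyperfine splittings from a first-derivative ESR spectrum
#'
#' On the smoothed derivative trace, `2T_par` is the separation between the
#' outermost maximum (low field) and the outermost minimum (high field);
#' `2T_perp` is the separation of the flanking inner extrema pair (the most
#' pronounced minimum between the outer maximum and the field center, and
#' the most pronounced maximum between the center and the outer minimum).
#' Extrema positions are refined by parabolic interpolation. Spectra whose
#' outer and inner separations nearly coincide look like freely rotating
#' (unincorporated) probe triplets and are flagged.
#'
#' @param s a [spectrum1d()] with a Gauss axis in ESR-derivative mode.
#' @param smoothing_window Savitzky-Golay window in points; `NULL` (default)
#'   picks a window near 2% of the trace length, the scale of the hyperfine
#'   features, so that noise cannot masquerade as an outer extremum.
#' @param unincorporated_below flag threshold on `2T_par - 2T_perp`, Gauss.
#' @return Object of class `hyperfine_measurement`: `two_T_par`,
#'   `two_T_perp`, `positions` (outer_max, inner_min, inner_max, outer_min,
#'   Gauss), `unincorporated`.
#' @export
measure_hyperfine <- function(s, smoothing_window = NULL, unincorporated_below = 8) {
  .check_spectrum(s, unit = "Gauss", mode = "ESR-derivative")
  x <- s$axis
  n <- length(x)
  if (is.null(smoothing_window)) smoothing_window <- max(7L, 2L * (n %/% 100L) + 1L)
  y <- .sgolay(s$intensity, smoothing_window)
  amp <- max(abs(y))
  if (amp <= 0) .stop_class("flat spectrum", "measurement_error")
  # extrema must clear an amplitude floor AND be prominent: noise riding on
  # a decaying wing tail creates local maxima above any absolute floor, but
  # their prominence after smoothing stays at the smoothed-noise scale
  sm_noise <- stats::mad(s$intensity - y) * sqrt(3 / smoothing_window)
  floor_lvl <- 0.05 * amp
  prom_lvl <- max(0.04 * amp, 10 * sm_noise)
  maxima <- .local_maxima(y)
  minima <- .local_minima(y)
  maxima <- maxima[y[maxima] > floor_lvl]
  minima <- minima[y[minima] < -floor_lvl]
  maxima <- maxima[.peak_prominence(y, maxima) >= prom_lvl]
  minima <- minima[.peak_prominence(-y, minima) >= prom_lvl]
  if (length(maxima) + length(minima) < 4L)
    .stop_class("fewer than 4 usable extrema in the derivative spectrum",
                "measurement_error")
  i_outer_max <- maxima[1]
  i_outer_min <- minima[length(minima)]
  if (i_outer_max >= i_outer_min)
    .stop_class("derivative spectrum lacks the low-field-max / high-field-min geometry",
                "measurement_error")
  kref <- smoothing_window
  p_outer_max <- .refine_quadratic(x, y, i_outer_max, kref)
  p_outer_min <- .refine_quadratic(x, -y, i_outer_min, kref)
  center <- (p_outer_max + p_outer_min) / 2
  lo_min <- minima[x[minima] > p_outer_max & x[minima] < center]
  hi_max <- maxima[x[maxima] > center & x[maxima] < p_outer_min]
  if (length(lo_min) == 0L || length(hi_max) == 0L)
    .stop_class("inner extrema pair not found", "measurement_error")
  i_inner_min <- lo_min[which.min(y[lo_min])]
  i_inner_max <- hi_max[which.max(y[hi_max])]
  p_inner_min <- .refine_quadratic(x, -y, i_inner_min, kref)
  p_inner_max <- .refine_quadratic(x, y, i_inner_max, kref)
  two_T_par <- p_outer_min - p_outer_max
  two_T_perp <- p_inner_max - p_inner_min
  if (!(two_T_par > two_T_perp && two_T_perp > 0))
    .stop_class("measured splittings violate 2T_par > 2T_perp > 0", "measurement_error")
  structure(list(two_T_par = two_T_par, two_T_perp = two_T_perp,
                 positions = c(outer_max = p_outer_max, inner_min = p_inner_min,
                               inner_max = p_inner_max, outer_min = p_outer_min),
                 unincorporated = (two_T_par - two_T_perp) < unincorporated_below),
            class = "hyperfine_measurement")
}

#' @export
print.hyperfine_measurement <- function(x, ...) {
  cat(sprintf("<hyperfine_measurement> 2T_par = %.2f G, 2T_perp = %.2f G%s\n",
              x$two_T_par, x$two_T_perp,
              if (x$unincorporated) " [unincorporated-probe pattern]" else ""))
  invisible(x)
}

#' Apparent order parameter from hyperfine splittings
#'
#' The default form reproduces the field formula as printed in the membrane
#' ESR literature exactly, with `T_par = two_T_par/2`, `T_perp =
#' two_T_perp/2`, polarity correction `C = 1.4 - 0.053 (T_par - T_perp)`
#' (half-separations, Gauss) and
#' `S = 1.723 (two_T_par - two_T_perp - C) / (T_par + two_T_perp + C)` --
#' note that the numerator uses full separations while the denominator mixes
#' a half and a full separation, so S can leave [0, 1]; it is reported
#' as-is. `form = "half-separation"` gives the conventional
#' Hubbell-McConnell-style expression in half-separations throughout,
#' `S = 1.723 (T_par - T_perp - C) / (T_par + 2 T_perp + C)`.
#'
#' @param m a [measure_hyperfine()] result (or any list with `two_T_par`
#'   and `two_T_perp` in Gauss).
#' @param form `"as-printed"` (default) or `"half-separation"`.
#' @return Object of class `esr_order`: `s`, `c_correction`, `form`.
#' @export
esr_order_parameter <- function(m, form = c("as-printed", "half-separation")) {
  form <- match.arg(form)
  t_par <- m$two_T_par / 2
  t_perp <- m$two_T_perp / 2
  cc <- 1.4 - 0.053 * (t_par - t_perp)
  s <- if (form == "as-printed")
    1.723 * (m$two_T_par - m$two_T_perp - cc) / (t_par + m$two_T_perp + cc)
  else
    1.723 * (t_par - t_perp - cc) / (t_par + 2 * t_perp + cc)
  structure(list(s = s, c_correction = cc, form = form), class = "esr_order")
}

#' @export
print.esr_order <- function(x, ...) {
  cat(sprintf("<esr_order> S = %.4f (C = %.3f G, %s form)\n",
              x$s, x$c_correction, x$form))
  invisible(x)
}

#' Order parameter versus temperature from a set of ESR spectra
#'
#' Applies [measure_hyperfine()] and [esr_order_parameter()] per
#' temperature; rows where measurement fails are kept with `NA` values and
#' `ok = FALSE` so the series is still usable downstream (the result feeds
#' [fit_transition()]).
#'
#' @param spectra list of `list(temperature, spectrum)` pairs (>= 3
#'   temperatures).
#' @param form passed to [esr_order_parameter()].
#' @return data.frame `(T_K, two_T_par_G, two_T_perp_G, C_G, S, ok)` sorted
#'   by temperature.
#' @export
order_temperature_profile <- function(spectra, form = "as-printed") {
  if (length(spectra) < 3L)
    .stop_class("at least 3 temperatures are required", "argument_error")
  rows <- lapply(spectra, function(el) {
    Tk <- el$temperature
    if (is.null(Tk)) Tk <- el[[1]]
    sp <- el$spectrum
    if (is.null(sp)) sp <- el[[2]]
    res <- tryCatch({
      hm <- measure_hyperfine(sp)
      eo <- esr_order_parameter(hm, form = form)
      data.frame(T_K = Tk, two_T_par_G = hm$two_T_par,
                 two_T_perp_G = hm$two_T_perp, C_G = eo$c_correction,
                 S = eo$s, ok = TRUE)
    }, error = function(e)
      data.frame(T_K = Tk, two_T_par_G = NA_real_, two_T_perp_G = NA_real_,
                 C_G = NA_real_, S = NA_real_, ok = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  out[order(out$T_K), , drop = FALSE]
}
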