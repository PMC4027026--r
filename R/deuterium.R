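# 2H powder-spectrum analysis: de-Pake-ing by regularized non-negative
# inversion, splitting extraction, order-parameter and fluidity profiles.

#' C-D order parameter from the average bond orientation angle
#'
#' `S_CD = (3 cos^2 beta - 1) / 2`, bounded in [-0.5, 1].
#'
#' @param beta angle in degrees.
#' @export
scd_from_angle <- function(beta) {
  (3 * cos(beta * pi / 180)^2 - 1) / 2
}

#' C-D order parameter from a quadrupolar splitting
#'
#' Inverts `delta_nu_q = (3/4) (e^2 q Q / h) S_CD` with the aliphatic C-D
#' quadrupolar coupling constant (170 kHz by default).
#'
#' @param delta_nu_q 90-degree quadrupolar splitting, kHz, >= 0.
#' @param coupling_constant e^2 q Q / h in kHz.
#' @export
order_parameter_from_splitting <- function(delta_nu_q, coupling_constant = 170) {
  if (any(delta_nu_q < 0))
    .stop_class("delta_nu_q must be >= 0", "argument_error")
  s <- delta_nu_q / (0.75 * coupling_constant)
  if (any(s > 1)) warning("order parameter exceeds 1; check the splitting or coupling constant")
  s
}

#' Symmetrize a spectrum about a center
#'
#' Returns the even part of the intensity about `center` (powder doublets are
#' symmetric; residual asymmetry is experimental artifact). The asymmetry
#' fraction `||odd|| / ||intensity||` is recorded in
#' `metadata$asymmetry_fraction`.
#'
#' @param s a [spectrum1d()].
#' @param center center of symmetry on the axis (0 kHz for 2H spectra).
#' @export
symmetrize <- function(s, center = 0) {
  .check_spectrum(s)
  if (center < min(s$axis) || center > max(s$axis))
    .stop_class("center lies outside the axis range", "argument_error")
  refl <- stats::approx(s$axis, s$intensity, xout = 2 * center - s$axis,
                        rule = 2)$y
  even <- (s$intensity + refl) / 2
  out <- s
  out$intensity <- even
  # asymmetry judged on a smoothed trace so that white noise (symmetric in
  # expectation) does not register as lineshape asymmetry
  sm <- .sgolay(s$intensity, max(7L, 2L * (length(s$axis) %/% 100L) + 1L))
  sm_refl <- stats::approx(s$axis, sm, xout = 2 * center - s$axis, rule = 2)$y
  total <- sqrt(sum(sm^2))
  out$metadata$asymmetry_fraction <-
    if (total > 0) sqrt(sum(((sm - sm_refl) / 2)^2)) / total else 0
  out$metadata$symmetrized_about <- center
  out
}

#' De-Pake a 2H powder spectrum
#'
#' Builds the explicit linear forward operator K mapping a unit weight at
#' 90-degree splitting Delta to its Lorentzian-broadened powder doublet
#' (the same uniform-cos(theta) orientation model as
#' [simulate_pake_spectrum()]), then solves the regularized non-negative
#' least-squares problem
#' `min ||K w - s||^2 + lambda ||D w||^2, w >= 0` (D = second difference)
#' with a fast active-set NNLS solver on the normal equations. The result is
#' the oriented-splitting distribution equivalent to a classical de-Paked
#' spectrum, with overlapping doublets resolved.
#'
#' `lambda = "auto"` picks the regularization from the corner of a discrete
#' L-curve over a log-spaced candidate grid (maximum Menger curvature of
#' (log residual norm, log seminorm)).
#'
#' @param s a [spectrum1d()] in kHz; symmetrized internally if needed (a
#'   warning is issued when the asymmetry fraction exceeds 5%).
#' @param grid splitting grid in kHz (default 0.5 to 40 by 0.1, capped by the
#'   axis range); the axis must cover the largest grid splitting.
#' @param lambda regularization parameter >= 0, or `"auto"`.
#' @param broadening_khz Lorentzian FWHM of the forward operator, kHz
#'   (match the intrinsic linewidth of the data).
#' @param n_orientations orientation grid size of the forward model.
#' @return Object of class `splitting_distribution`: `grid`, non-negative
#'   `weights`, `lambda`, and the relative forward `residual`
#'   `||Kw - s|| / ||s||`.
#' @export
depake <- function(s, grid = NULL, lambda = "auto", broadening_khz = 0.5,
                   n_orientations = 2000) {
  .check_spectrum(s, unit = "kHz")
  if (all(abs(s$intensity) < .Machine$double.eps))
    .stop_class("all-zero spectrum cannot be de-Paked", "degenerate_input_error")
  if (is.null(s$metadata$symmetrized_about)) {
    s <- symmetrize(s, 0)
    if (s$metadata$asymmetry_fraction > 0.05)
      warning(sprintf("spectrum asymmetry fraction %.1f%% exceeds 5%%",
                      100 * s$metadata$asymmetry_fraction))
  }
  axis_max <- min(abs(min(s$axis)), abs(max(s$axis)))
  if (is.null(grid)) grid <- seq(0.5, min(40, axis_max), by = 0.1)
  if (max(grid) > axis_max)
    .stop_class(sprintf(
      "grid extends to %g kHz but the axis only covers +/- %g kHz (0-degree shoulders unobserved)",
      max(grid), axis_max), "range_error")
  p <- length(grid)
  n <- length(s$axis)
  u <- (seq_len(n_orientations) - 0.5) / n_orientations
  orient <- (3 * u^2 - 1) / 2
  K <- matrix(0, n, p)
  for (j in seq_len(p)) {
    nu <- grid[j] * orient
    col <- .bin_deltas(s$axis, c(nu, -nu),
                       rep(1 / (2 * n_orientations), 2 * n_orientations))
    K[, j] <- .lorentz_conv(s$axis, col, broadening_khz)
  }
  y <- s$intensity
  KtK <- crossprod(K)
  Kty <- drop(crossprod(K, y))
  D <- .second_diff(p)
  DtD <- crossprod(D)
  scale0 <- mean(diag(KtK))
  solve_one <- function(lam) .fnnls(KtK + lam * DtD, Kty)
  if (identical(lambda, "auto")) {
    cand <- 10^seq(-7, -1, length.out = 7) * scale0
    sols <- lapply(cand, solve_one)
    lres <- vapply(sols, function(w) log(sqrt(sum((K %*% w - y)^2)) + 1e-300), numeric(1))
    lsem <- vapply(sols, function(w) log(sqrt(sum((D %*% w)^2)) + 1e-300), numeric(1))
    curv <- rep(-Inf, length(cand))
    for (i in 2:(length(cand) - 1)) {
      a <- c(lres[i - 1], lsem[i - 1]); b <- c(lres[i], lsem[i]); cc <- c(lres[i + 1], lsem[i + 1])
      num <- 2 * abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2]))
      den <- sqrt(sum((b - a)^2)) * sqrt(sum((cc - b)^2)) * sqrt(sum((cc - a)^2))
      if (den > 0) curv[i] <- num / den
    }
    pick <- which.max(curv)
    lambda <- cand[pick]
    w <- sols[[pick]]
  } else {
    if (!is.numeric(lambda) || lambda < 0)
      .stop_class("lambda must be >= 0 or \"auto\"", "argument_error")
    w <- solve_one(lambda)
  }
  resid <- sqrt(sum((K %*% w - y)^2)) / sqrt(sum(y^2))
  structure(list(grid = grid, weights = w, lambda = lambda, residual = resid,
                 broadening_khz = broadening_khz),
            class = "splitting_distribution")
}

#' @export
print.splitting_distribution <- function(x, ...) {
  cat(sprintf("<splitting_distribution> %d-point grid %.2g..%.2g kHz, lambda = %.3g, rel. residual %.3g\n",
              length(x$grid), min(x$grid), max(x$grid), x$lambda, x$residual))
  invisible(x)
}

#' Extract discrete quadrupolar splittings from a de-Paked distribution
#'
#' Peak-picks local maxima of the weight vector above a noise floor (3x the
#' median absolute deviation of the weights, with a small relative-height
#' guard), merges peaks closer than `min_separation_khz` into their weighted
#' centroid, refines each position by a local weighted centroid, and returns
#' the components in descending weight order.
#'
#' @param d a `splitting_distribution` from [depake()].
#' @param min_separation_khz peaks closer than this merge into one.
#' @param max_components cap on the number of returned components.
#' @return data.frame `(delta_nu_q, weight)` in descending weight order, with
#'   attribute `empty = TRUE` (plus a warning) when nothing rises above the
#'   floor.
#' @export
extract_splittings <- function(d, min_separation_khz = 1, max_components = 10) {
  stopifnot(inherits(d, "splitting_distribution"))
  w <- d$weights
  g <- d$grid
  floor_lvl <- max(3 * stats::mad(w, center = 0), 0.005 * max(w))
  idx <- .local_maxima(w)
  idx <- idx[w[idx] > floor_lvl]
  # endpoints can carry mass the interior-maxima scan misses
  for (e in c(1L, length(w)))
    if (w[e] > floor_lvl && w[e] >= max(w[max(1, e - 1):min(length(w), e + 1)]))
      idx <- sort(unique(c(idx, e)))
  if (length(idx) == 0L) {
    warning("no splitting components above the noise floor")
    out <- data.frame(delta_nu_q = numeric(0), weight = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  # partition the grid at the minima between adjacent picked peaks
  bounds <- c(1L, vapply(seq_len(length(idx) - 1L), function(k) {
    lo <- idx[k]; hi <- idx[k + 1L]
    lo + which.min(w[lo:hi]) - 1L
  }, integer(1)), length(w))
  comps <- lapply(seq_along(idx), function(k) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    seg <- lo:hi
    seg <- seg[w[seg] > floor_lvl / 3]
    if (length(seg) == 0L) seg <- idx[k]
    pos <- sum(g[seg] * w[seg]) / sum(w[seg])
    c(pos = pos, weight = sum(w[seg]))
  })
  comps <- do.call(rbind, comps)
  # merge components closer than min_separation
  repeat {
    o <- order(comps[, "pos"])
    comps <- comps[o, , drop = FALSE]
    gaps <- diff(comps[, "pos"])
    k <- which(gaps < min_separation_khz)
    if (length(k) == 0L) break
    k <- k[1]
    wsum <- comps[k, "weight"] + comps[k + 1, "weight"]
    merged <- c(pos = (comps[k, "pos"] * comps[k, "weight"] +
                         comps[k + 1, "pos"] * comps[k + 1, "weight"]) / wsum,
                weight = wsum)
    comps <- rbind(comps[-c(k, k + 1), , drop = FALSE], merged)
  }
  comps <- comps[order(-comps[, "weight"]), , drop = FALSE]
  if (nrow(comps) > max_components) comps <- comps[seq_len(max_components), , drop = FALSE]
  out <- data.frame(delta_nu_q = comps[, "pos"], weight = comps[, "weight"])
  rownames(out) <- NULL
  attr(out, "empty") <- FALSE
  out
}

#' Assign chain-position labels to extracted splittings
#'
#' Acyl-chain fluidity decreases from the terminal methyl to the carbons
#' near the glycerol backbone, so splittings sorted ascending map to: the
#' smallest -> CD3, the largest -> the C2-C8 plateau (treated as one
#' effective component), intermediates -> C14 down to C9 in order.
#'
#' @param splittings numeric vector of splittings (kHz) or the data.frame
#'   from [extract_splittings()]; at least 2 values.
#' @param system system name stored in the profile.
#' @param temperature temperature in K.
#' @param coupling_constant e^2 q Q / h in kHz (see
#'   [order_parameter_from_splitting()]).
#' @return Object of class `fluidity_profile`: a data.frame
#'   `(label, delta_nu_q, s_cd, weight)` sorted by ascending splitting plus
#'   `system`, `temperature` and `coupling_constant` attributes.
#' @export
assign_profile <- function(splittings, system = "", temperature = NA_real_,
                           coupling_constant = 170) {
  if (is.data.frame(splittings)) {
    wts <- splittings$weight
    splittings <- splittings$delta_nu_q
  } else wts <- rep(NA_real_, length(splittings))
  if (length(splittings) < 2L)
    .stop_class("at least 2 splittings are needed to anchor CD3 and the plateau",
                "assignment_error")
  o <- order(splittings)
  splittings <- splittings[o]
  wts <- wts[o]
  n <- length(splittings)
  labels <- if (n == 2L) c("CD3", "plateau")
            else c("CD3", paste0("C", 14:(14 - (n - 3L))), "plateau")
  prof <- data.frame(label = labels, delta_nu_q = splittings,
                     s_cd = order_parameter_from_splitting(splittings, coupling_constant),
                     weight = wts, stringsAsFactors = FALSE)
  structure(list(profile = prof, system = system, temperature = temperature,
                 coupling_constant = coupling_constant),
            class = "fluidity_profile")
}

#' @export
print.fluidity_profile <- function(x, ...) {
  cat(sprintf("<fluidity_profile> %s at %s K (e2qQ/h = %g kHz)\n",
              if (nzchar(x$system)) x$system else "(unnamed)",
              format(x$temperature), x$coupling_constant))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fluidity_profile <- function(x, ...) x$profile

#' Relative local fluidity of a system against a reference
#'
#' Per matched chain position, `R = (QS_X - QS_ref) / QS_ref` where QS is
#' the quadrupolar splitting: R < 0 means local fluidization relative to the
#' reference membrane, R > 0 rigidification.
#'
#' @param profile_x,profile_ref [assign_profile()] outputs with matching
#'   position labels.
#' @return Object of class `relative_fluidity`: data.frame
#'   `(label, qs_x, qs_ref, R)` plus the reference system name.
#' @export
relative_fluidity <- function(profile_x, profile_ref) {
  stopifnot(inherits(profile_x, "fluidity_profile"),
            inherits(profile_ref, "fluidity_profile"))
  px <- profile_x$profile
  pr <- profile_ref$profile
  if (!setequal(px$label, pr$label) || nrow(px) != nrow(pr))
    .stop_class("position labels of the two profiles do not match", "alignment_error")
  pr <- pr[match(px$label, pr$label), ]
  if (any(pr$delta_nu_q == 0))
    .stop_class("reference splitting of zero: relative fluidity undefined",
                "argument_error")
  out <- data.frame(label = px$label, qs_x = px$delta_nu_q, qs_ref = pr$delta_nu_q,
                    R = (px$delta_nu_q - pr$delta_nu_q) / pr$delta_nu_q,
                    stringsAsFactors = FALSE)
  structure(list(table = out, system = profile_x$system,
                 reference = profile_ref$system),
            class = "relative_fluidity")
}

#' @export
print.relative_fluidity <- function(x, ...) {
  cat(sprintf("<relative_fluidity> %s vs %s\n",
              if (nzchar(x$system)) x$system else "X",
              if (nzchar(x$reference)) x$reference else "reference"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.relative_fluidity <- function(x, ...) x$table
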