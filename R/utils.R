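# Internal numerics shared across modules. None of these are exported.

# Run code with a temporary RNG seed; seed = NULL leaves the RNG stream alone.
.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), force(code))
}

.is_uniform_axis <- function(x, tol = 1e-6) {
  d <- diff(x)
  all(abs(d - d[1]) <= tol * abs(d[1]))
}

# Convolve a uniformly sampled trace with a unit-area Lorentzian of the given
# full width at half maximum. Kernel truncated at 60 half-widths (tail mass
# there is < 1e-2 of a percent of the peak and numerically irrelevant).
.lorentz_conv <- function(axis, y, fwhm) {
  if (fwhm <= 0) return(y)
  dx <- axis[2] - axis[1]
  g <- fwhm / 2
  m <- min(length(y) - 1L, as.integer(ceiling(60 * g / dx)))
  if (m < 1L) return(y)
  k <- (-m:m) * dx
  kern <- (g / pi) / (k^2 + g^2)
  kern <- kern / sum(kern)
  out <- stats::convolve(y, rev(kern), type = "open")
  out[(m + 1L):(m + length(y))]
}

# Unit-height Lorentzian profile with half width at half maximum g.
.lorentz_profile <- function(x, x0, g) g^2 / ((x - x0)^2 + g^2)

# Deposit point masses onto a uniform axis with linear (first-order) binning.
.bin_deltas <- function(axis, pos, wt) {
  n <- length(axis)
  dx <- axis[2] - axis[1]
  fi <- (pos - axis[1]) / dx
  i0 <- floor(fi)
  fr <- fi - i0
  idx <- c(i0 + 1, i0 + 2)
  w <- c(wt * (1 - fr), wt * fr)
  ok <- idx >= 1 & idx <= n
  y <- numeric(n)
  if (any(ok)) {
    acc <- rowsum(w[ok], idx[ok])
    y[as.integer(rownames(acc))] <- acc[, 1]
  }
  y
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

# Savitzky-Golay smoothing / differentiation with guard rails on window size.
.sgolay <- function(y, window, deriv = 0L, dx = 1) {
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  window <- max(window, if (deriv > 0L) 5L else 3L)
  if (window >= n) window <- if (n %% 2L == 0L) n - 1L else n - 2L
  if (window < 3L) return(if (deriv == 0L) y else rep(0, n))
  p <- min(3L, window - 2L)
  out <- signal::sgolayfilt(y, p = p, n = window, m = deriv)
  if (deriv > 0L) out <- out / dx^deriv
  out
}

# Indices of strict local maxima (plateaus resolved to their first point).
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

.local_minima <- function(y) .local_maxima(-y)

# Windowed quadratic refinement of an extremum: least-squares parabola over
# +/- k points around index i (noise-robust for broad features, unlike the
# 3-point vertex). Falls back to x[i] if the vertex escapes the window.
.refine_quadratic <- function(x, y, i, k) {
  n <- length(x)
  sel <- max(1L, i - k):min(n, i + k)
  if (length(sel) < 5L) return(.parabolic_refine(x, y, i))
  xc <- x[sel] - x[i]
  fit <- stats::lm.fit(cbind(1, xc, xc^2), y[sel])
  cf <- unname(fit$coefficients)
  if (!is.finite(cf[3]) || cf[3] == 0) return(x[i])
  v <- -cf[2] / (2 * cf[3])
  if (abs(v) > abs(x[sel[length(sel)]] - x[i]) ||
      abs(v) > abs(x[sel[1]] - x[i])) return(x[i])
  x[i] + v
}

# Prominence of each local maximum: drop from the peak to the higher of the
# two valley floors separating it from taller terrain (or the trace ends).
.peak_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    left <- y[seq_len(i)]
    right <- y[i:length(y)]
    lv <- if (any(left > y[i])) min(left[max(which(left > y[i])):i]) else min(left)
    rv <- if (any(right > y[i])) min(right[1:min(which(right > y[i]))]) else min(right)
    y[i] - max(lv, rv)
  }, numeric(1))
}

# Vertex of the parabola through (x[i-1..i+1], y[i-1..i+1]); falls back to x[i].
.parabolic_refine <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(x[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < .Machine$double.eps * (abs(y1) + abs(y2) + abs(y3) + 1)) return(x[i])
  d <- 0.5 * (y1 - y3) / den
  d <- max(min(d, 1), -1)
  x[i] + d * (x[i + 1L] - x[i])
}

# Fast non-negative least squares (Bro & de Jong 1997) on the normal
# equations: minimizes ||Zw - y||^2 with w >= 0 given ZtZ and Zty.
.fnnls <- function(ZtZ, Zty, tol = NULL) {
  p <- length(Zty)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(diag(ZtZ)))
  P <- logical(p)
  w <- numeric(p)
  grad <- Zty - drop(ZtZ %*% w)
  outer_it <- 0L
  max_outer <- 30L * p
  solve_sub <- function(act) {
    A <- ZtZ[act, act, drop = FALSE]
    b <- Zty[act]
    tryCatch(solve(A, b), error = function(e) {
      solve(A + diag(1e-10 * mean(diag(A)), nrow(A)), b)
    })
  }
  while (any(!P) && any(grad[!P] > tol) && outer_it < max_outer) {
    outer_it <- outer_it + 1L
    cand <- which(!P)
    P[cand[which.max(grad[cand])]] <- TRUE
    s <- numeric(p)
    s[P] <- solve_sub(P)
    inner_it <- 0L
    while (any(s[P] <= 0) && inner_it < max_outer) {
      inner_it <- inner_it + 1L
      viol <- P & (s <= 0)
      alpha <- min(w[viol] / (w[viol] - s[viol]))
      w <- w + alpha * (s - w)
      P[P & (w <= .Machine$double.eps)] <- FALSE
      s <- numeric(p)
      if (any(P)) s[P] <- solve_sub(P)
    }
    w <- s
    grad <- Zty - drop(ZtZ %*% w)
  }
  pmax(w, 0)
}

# Second-difference operator (p-2) x p used as the roughness penalty.
.second_diff <- function(p) {
  if (p < 3L) return(matrix(0, 0, p))
  D <- matrix(0, p - 2L, p)
  for (i in seq_len(p - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
  D
}

.stop_class <- function(msg, class) {
  stop(structure(class = c(class, "spinorder_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
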