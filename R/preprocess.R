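# Preprocessing: raw stylus samples -> smoothed trajectory -> tangential
# velocity -> movement window.  Smoothing is least-squares cubic B-spline
# regression on a fixed knot grid (a knot every `knot_every` samples), so the
# velocity comes from the analytic derivative of the fitted spline rather than
# finite differences of noisy samples.

#' Flag discontinuously recorded trials
#'
#' A trial is excluded when any inter-sample time gap exceeds
#' `max_gap_samples` nominal sample periods, i.e. the stylus was not recorded
#' continuously from start to end.
#'
#' @param samples Tibble with columns `t`, `x`, `y` for one trial.
#' @param sample_rate_hz Nominal sampling rate (Hz).
#' @param max_gap_samples Continuity threshold in sample periods (default 3).
#' @return List with `excluded` (logical), `reason` (string or `NA`), and
#'   `max_gap_s` (largest inter-sample interval, s).
#' @export
exclude_trial <- function(samples, sample_rate_hz = 160, max_gap_samples = 3) {
  gap <- max(diff(samples$t))
  if (gap > max_gap_samples / sample_rate_hz) {
    list(excluded = TRUE, reason = "discontinuous recording", max_gap_s = gap)
  } else {
    list(excluded = FALSE, reason = NA_character_, max_gap_s = gap)
  }
}

#' Fit a fixed-knot smoothing spline to one trial
#'
#' Least-squares cubic B-spline regression of x(t) and y(t) with interior
#' knots at every `knot_every`-th sample time. Derivatives are analytic
#' (from the spline basis).
#'
#' @param samples Tibble with columns `t`, `x`, `y`.
#' @param knot_every Knot spacing in samples (default 6).
#' @return A `smooth_trajectory`: list with the knot vector, coefficient
#'   matrix, sample times, and `residual_rms` (pooled per-axis residual, cm).
#' @export
smooth_trajectory <- function(samples, knot_every = 6) {
  t <- samples$t
  n <- length(t)
  if (n < 2 * knot_every + 1) {
    stop("too few samples to fit the smoothing spline (need at least ",
         2 * knot_every + 1, ")", call. = FALSE)
  }
  idx <- seq(1L, n, by = knot_every)
  if (tail(idx, 1) != n) idx <- c(idx, n)
  interior <- t[idx][-c(1L, length(idx))]
  ord <- 4L
  aknots <- c(rep(t[1], ord), interior, rep(t[n], ord))
  B <- splines::splineDesign(aknots, t, ord = ord)
  fit <- stats::lm.fit(B, cbind(x = samples$x, y = samples$y))
  res <- fit$residuals
  structure(
    list(aknots = aknots, coef = fit$coefficients, t = t,
         range = range(t),
         residual_rms = sqrt(mean(res^2))),
    class = "smooth_trajectory"
  )
}

#' Evaluate a smoothed trajectory (or its derivatives)
#'
#' @param st A [smooth_trajectory()].
#' @param t Times to evaluate at (clamped to the fitted range).
#' @param deriv Derivative order: 0 (position), 1 (velocity) or 2
#'   (acceleration).
#' @return Tibble with `t`, `x`, `y`.
#' @export
eval_trajectory <- function(st, t = st$t, deriv = 0) {
  t <- pmin(pmax(t, st$range[1]), st$range[2])
  B <- splines::splineDesign(st$aknots, t, ord = 4L,
                             derivs = rep(deriv, length(t)))
  p <- B %*% st$coef
  tibble::new_tibble(list(t = t, x = p[, 1], y = p[, 2]), nrow = length(t))
}

#' @export
print.smooth_trajectory <- function(x, ...) {
  cat("<smooth_trajectory> ", length(x$t), " samples over [",
      signif(x$range[1], 4), ", ", signif(x$range[2], 4), "] s; residual RMS ",
      signif(x$residual_rms, 3), " cm\n", sep = "")
  invisible(x)
}

#' Construct a tangential velocity profile
#'
#' @param t Sample times (s).
#' @param v Tangential speed (cm/s), non-negative.
#' @return A `velocity_profile` tibble (`t`, `v`) with attribute `v_peak`.
#' @export
velocity_profile <- function(t, v) {
  stopifnot(length(t) == length(v), all(v >= -1e-12))
  v <- pmax(v, 0)
  out <- tibble::new_tibble(list(t = t, v = v), nrow = length(t))
  structure(out, class = c("velocity_profile", class(out)),
            v_peak = max(v))
}

#' Tangential velocity of a smoothed trajectory
#'
#' v(t) = sqrt(x'(t)^2 + y'(t)^2), evaluated from the analytic spline
#' derivative on the sample grid.
#'
#' @param st A [smooth_trajectory()].
#' @param t Times (defaults to the original sample times).
#' @return A [velocity_profile()].
#' @export
tangential_velocity <- function(st, t = st$t) {
  d <- eval_trajectory(st, t, deriv = 1)
  velocity_profile(t, sqrt(d$x^2 + d$y^2))
}

# indices of local maxima (plateaus collapse to their first sample)
local_maxima_idx <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(diff(sign(diff(v))) < 0) + 1L
  # plateau handling: rle-based scan for flat tops
  if (any(diff(v) == 0)) {
    idx <- integer(0)
    i <- 2L
    while (i <= n - 1L) {
      if (v[i] > v[i - 1L]) {
        j <- i
        while (j < n && v[j + 1L] == v[j]) j <- j + 1L
        if (j < n && v[j + 1L] < v[j]) idx <- c(idx, i)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  idx
}

# topographic prominence of peaks at `idx` within profile v
peak_prominence <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1L)]
    hl <- which(left > h)
    lmin <- if (length(hl)) min(left[(max(hl) + 1L):(i - 1L)]) else min(left)
    right <- v[(i + 1L):length(v)]
    hr <- which(right > h)
    rmin <- if (length(hr)) min(right[seq_len(min(hr) - 1L)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
}

# local maxima passing the relative-prominence rule
qualifying_peaks <- function(v, prominence_frac = 0.05) {
  idx <- local_maxima_idx(v)
  if (!length(idx)) return(integer(0))
  prom <- peak_prominence(v, idx)
  idx[prom >= prominence_frac * max(v)]
}

#' Detect movement onset and offset
#'
#' Onset is the last time, before the first tangential-velocity peak
#' exceeding `peak_frac` of the peak tangential velocity, at which the
#' velocity is below `onset_frac` of the peak velocity. Offset is the last
#' time the velocity exceeds `onset_frac` of the peak velocity. Peaks are
#' local maxima with topographic prominence of at least `prominence_frac`
#' of the peak velocity (suppresses noise ripples).
#'
#' @param vp A [velocity_profile()].
#' @param onset_frac Relative onset/offset threshold (default 0.05).
#' @param peak_frac Relative height a peak must reach to anchor the onset
#'   search (default 0.35).
#' @param prominence_frac Relative prominence for peak qualification.
#' @param min_above_s Minimum duration (s) a supra-threshold run must last to
#'   count for the offset rule. Spline-smoothed sensor noise is correlated
#'   over roughly one knot interval, so isolated ripple excursions above the
#'   5% threshold during the terminal dwell would otherwise drag the offset
#'   to the end of the recording. Runs shorter than this are ignored; if no
#'   run qualifies, the last crossing is used as a fallback.
#' @return A `movement_window`: list with `t_on`, `t_off`, `duration`.
#' @export
detect_onset_offset <- function(vp, onset_frac = 0.05, peak_frac = 0.35,
                                prominence_frac = 0.05, min_above_s = 0.05) {
  v <- vp$v; t <- vp$t
  v_peak <- max(v)
  if (v_peak <= 0) stop("flat zero velocity profile", call. = FALSE)
  peaks <- qualifying_peaks(v, prominence_frac)
  peaks <- peaks[v[peaks] > peak_frac * v_peak]
  if (!length(peaks)) {
    stop("no velocity peak exceeds ", peak_frac, " of the peak velocity",
         call. = FALSE)
  }
  first_pk <- peaks[1]
  before <- which(v[seq_len(first_pk)] < onset_frac * v_peak)
  if (!length(before)) {
    stop("movement onset undetectable: velocity never drops below ",
         onset_frac, " of peak before the first qualifying peak",
         call. = FALSE)
  }
  t_on <- t[max(before)]
  above <- v > onset_frac * v_peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_ok <- r$values & (t[ends] - t[starts] >= min_above_s)
  i_off <- if (any(run_ok)) ends[max(which(run_ok))] else max(which(above))
  t_off <- t[i_off]
  if (!(t_on < t_off)) {
    stop("degenerate movement window (onset >= offset)", call. = FALSE)
  }
  structure(list(t_on = t_on, t_off = t_off, duration = t_off - t_on),
            class = "movement_window")
}

#' Movement duration
#'
#' @param win A `movement_window` from [detect_onset_offset()].
#' @return Duration in seconds (`t_off - t_on`).
#' @export
movement_duration <- function(win) win$t_off - win$t_on

#' Restrict a velocity profile to a movement window
#'
#' @param vp A [velocity_profile()].
#' @param win A `movement_window`.
#' @return The windowed [velocity_profile()].
#' @export
window_profile <- function(vp, win) {
  keep <- vp$t >= win$t_on & vp$t <= win$t_off
  velocity_profile(vp$t[keep], vp$v[keep])
}

#' Time-normalize a velocity profile
#'
#' Resamples the profile at `n_points` equally spaced normalized times on
#' \[0, 1\] by linear interpolation, so profiles of different durations can be
#' averaged or overlaid.
#'
#' @param vp A [velocity_profile()] (typically already windowed).
#' @param n_points Number of output points (>= 2), default 100.
#' @return Tibble with `tau` (normalized time) and `v`.
#' @export
time_normalize <- function(vp, n_points = 100) {
  if (n_points < 2) stop("`n_points` must be at least 2", call. = FALSE)
  tau_in <- (vp$t - vp$t[1]) / (vp$t[nrow(vp)] - vp$t[1])
  out_tau <- seq(0, 1, length.out = n_points)
  v_out <- stats::approx(tau_in, vp$v, xout = out_tau)$y
  tibble::tibble(tau = out_tau, v = v_out)
}
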