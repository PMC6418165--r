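# Trial-level outcome measures: peak/trough structure and the coarticulation
# score, number of velocity peaks, path offset (curvature proxy) and spatial
# error, plus the normalization conventions.

# parabolic refinement of an extremum height from three samples
refine_extremum <- function(t, v, i) {
  if (i <= 1L || i >= length(v)) return(list(t = t[i], h = v[i]))
  y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < 1e-300) return(list(t = t[i], h = v[i]))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  h <- y2 - 0.25 * (y1 - y3) * delta
  dt <- if (i < length(t)) t[i + 1L] - t[i] else t[i] - t[i - 1L]
  list(t = t[i] + delta * dt, h = h)
}

# closest-approach times of a sampled path to the B, C, D target centers
boundary_times <- function(positions, layout) {
  ctr <- target_centers(layout)
  vapply(c("B", "C", "D"), function(lb) {
    d2 <- (positions$x - ctr[lb, 1])^2 + (positions$y - ctr[lb, 2])^2
    positions$t[which.min(d2)]
  }, numeric(1))
}

# Shoulder (inflection) point of a merged peak region.
#
# Prominence-based qualification drops a peak-trough pair while a faint
# sub-threshold local max/min pair can still exist. In that regime the
# inflection lies between the faint extrema and its height is taken as the
# pair midpoint -- this keeps the score continuous across the 4 -> 3
# transition (the faint pair's heights enter the score as their mean rather
# than vanishing abruptly) and is stable, unlike picking among shallow
# minima of |v'|. Once the pair has truly annihilated, the unique interior
# minimum of |v'| (not itself an extremum of v) marks the shoulder;
# `t_pref`, the passage time of the merged boundary target, breaks ties.
find_shoulder <- function(t, v, lo, hi, max_idx, t_pref = NULL) {
  idx <- lo:hi
  if (length(idx) < 7L) {
    i <- idx[which.min(abs(v[idx] - mean(v[idx])))]
    return(list(t = t[i], h = v[i], idx = i))
  }
  # faint (sub-prominence) extremum pair still present in the region?
  vv <- v[idx]
  d <- diff(vv)
  ext <- which(d[-1] * d[-length(d)] < 0) + 1L   # strict sign changes
  ext <- ext[abs(idx[ext] - max_idx) > 2L]
  ext <- ext[ext > 2L & ext < length(idx) - 1L]
  if (length(ext) >= 2L) {
    gaps <- diff(ext)
    j <- which.min(gaps)
    i1 <- idx[ext[j]]; i2 <- idx[ext[j + 1L]]
    return(list(t = (t[i1] + t[i2]) / 2, h = (v[i1] + v[i2]) / 2,
                idx = as.integer(round((i1 + i2) / 2))))
  }
  if (length(ext) == 1L) {
    i <- idx[ext]
    return(list(t = t[i], h = v[i], idx = i))
  }
  # truly merged: interior minimum of |v'| away from the maximum
  dv <- c(NA, diff(vv) / diff(t[idx]))
  g <- abs(dv)
  interior <- 3:(length(idx) - 2L)
  cand <- interior[which(g[interior] < g[interior - 1L] &
                           g[interior] <= g[interior + 1L])]
  cand <- cand[abs(idx[cand] - max_idx) > 2L]
  if (!length(cand)) {
    far <- interior[abs(idx[interior] - max_idx) > 2L]
    if (!length(far)) far <- interior
    cand <- far[which.min(g[far])]
  }
  j <- if (!is.null(t_pref) && length(cand) > 1L) {
    cand[which.min(abs(t[idx[cand]] - t_pref))]
  } else {
    cand[which.min(g[cand])]
  }
  i <- idx[j]
  list(t = t[i], h = v[i], idx = i)
}

#' Extract the peak/trough structure of a velocity profile
#'
#' Finds up to four qualifying velocity peaks (local maxima with topographic
#' prominence of at least `prominence_frac` of the profile maximum; if more
#' than four qualify, the four largest are kept, ties broken by earlier time)
#' and the troughs between them (the lowest point between consecutive kept
#' peaks). When coarticulation has merged a peak-trough pair away (fewer than
#' four peaks), the inflection point of the merged region supplies both the
#' missing peak and the missing trough height; these entries are flagged as
#' substitutions.
#'
#' Trough ordinals map to the segment boundaries B (1st), C (2nd), D (3rd).
#' When `positions` and `layout` are supplied, observed troughs are assigned
#' to boundaries by the trajectory's closest-approach times to B, C, D;
#' otherwise the reversal at C is assumed to produce the lowest trough and
#' ordinals are assigned around it.
#'
#' @param vp A windowed [velocity_profile()].
#' @param positions Optional tibble `t`, `x`, `y` of the windowed trajectory.
#' @param layout Optional [target_layout()] (required with `positions`).
#' @param prominence_frac Relative prominence for peak qualification.
#' @param refine Parabolically refine extremum heights from neighbouring
#'   samples (default `TRUE`).
#' @return A `peak_structure`: list with tibbles `peaks` (ordinal, t, height,
#'   substituted) and `troughs` (ordinal, t, height, substituted), and
#'   `n_observed_peaks`.
#' @export
find_peak_structure <- function(vp, positions = NULL, layout = NULL,
                                prominence_frac = 0.05, refine = TRUE) {
  v <- vp$v; t <- vp$t
  pk_idx <- qualifying_peaks(v, prominence_frac)
  if (!length(pk_idx)) {
    stop("no qualifying velocity peaks: measure undefined", call. = FALSE)
  }
  if (length(pk_idx) > 4L) {
    ord <- order(-v[pk_idx], pk_idx)   # largest first, earlier wins ties
    pk_idx <- sort(pk_idx[ord[1:4]])
  }
  k <- length(pk_idx)
  ext <- function(i) {
    e <- if (refine) refine_extremum(t, v, i) else list(t = t[i], h = v[i])
    e$h <- max(e$h, 0)   # v >= 0: parabola undershoot clamps to zero
    e
  }
  pk <- lapply(pk_idx, ext)

  tr_idx <- integer(0)
  if (k >= 2L) {
    tr_idx <- vapply(seq_len(k - 1L), function(j) {
      span <- (pk_idx[j] + 1L):(pk_idx[j + 1L] - 1L)
      span[which.min(v[span])]
    }, integer(1))
  }
  tr <- lapply(tr_idx, ext)

  if (k == 4L) {
    peaks <- tibble::tibble(
      ordinal = 1:4,
      t = vapply(pk, `[[`, 0, "t"),
      height = vapply(pk, `[[`, 0, "h"),
      substituted = FALSE
    )
    troughs <- tibble::tibble(
      ordinal = 1:3,
      t = vapply(tr, `[[`, 0, "t"),
      height = vapply(tr, `[[`, 0, "h"),
      substituted = FALSE
    )
    return(structure(list(peaks = peaks, troughs = troughs,
                          n_observed_peaks = k),
                     class = "peak_structure"))
  }

  # fewer than 4 peaks: decide which boundary ordinals the observed troughs
  # occupy, then substitute the inflection point for each missing pair
  n_tr <- length(tr_idx)                # k - 1 observed troughs
  tr_t <- vapply(tr, `[[`, 0, "t")
  ords <- assign_trough_ordinals(tr_t, vapply(tr, `[[`, 0, "h"),
                                 positions, layout)
  missing <- setdiff(1:3, ords)

  troughs <- tibble::tibble(ordinal = ords, t = tr_t,
                            height = vapply(tr, `[[`, 0, "h"),
                            substituted = FALSE)
  peaks <- tibble::tibble(ordinal = NA_integer_,
                          t = vapply(pk, `[[`, 0, "t"),
                          height = vapply(pk, `[[`, 0, "h"),
                          substituted = FALSE)

  bt <- if (!is.null(positions) && !is.null(layout)) {
    boundary_times(positions, layout)
  } else NULL
  for (m in missing) {
    # merged region: span of the observed peak adjacent to boundary m,
    # bounded by neighbouring observed troughs / window edges
    bnd_idx <- c(1L, tr_idx, length(v))
    merged_peak_j <- if (m == 1L) 1L else k   # pair (1,2) or (3,4) merged
    lo <- bnd_idx[merged_peak_j]
    hi <- bnd_idx[merged_peak_j + 1L]
    sh <- find_shoulder(t, v, lo, hi, pk_idx[merged_peak_j],
                        t_pref = if (!is.null(bt)) bt[[m]] else NULL)
    peaks <- dplyr::bind_rows(
      peaks, tibble::tibble(ordinal = NA_integer_, t = sh$t,
                            height = sh$h, substituted = TRUE))
    troughs <- dplyr::bind_rows(
      troughs, tibble::tibble(ordinal = m, t = sh$t, height = sh$h,
                              substituted = TRUE))
  }
  peaks <- peaks[order(peaks$t), ]
  peaks$ordinal <- seq_len(nrow(peaks))
  troughs <- troughs[order(troughs$ordinal), ]
  structure(list(peaks = peaks, troughs = troughs, n_observed_peaks = k),
            class = "peak_structure")
}

# Assign observed trough times to boundary ordinals 1 (B), 2 (C), 3 (D).
assign_trough_ordinals <- function(tr_t, tr_h, positions, layout) {
  n_tr <- length(tr_t)
  if (n_tr == 0L) return(integer(0))
  if (n_tr >= 3L) return(seq_len(n_tr))
  if (!is.null(positions) && !is.null(layout)) {
    bt <- boundary_times(positions, layout)
    # order-preserving assignment minimizing total time mismatch
    subsets <- utils::combn(3L, n_tr)
    cost <- apply(subsets, 2, function(s) sum(abs(tr_t - bt[s])))
    return(subsets[, which.min(cost)])
  }
  # fallback: the reversal at C gives the lowest trough (ordinal 2)
  if (n_tr == 1L) return(2L)
  if (which.min(tr_h) == 1L) c(2L, 3L) else c(1L, 2L)
}

#' @export
print.peak_structure <- function(x, ...) {
  cat("<peak_structure> ", x$n_observed_peaks, " observed peak(s)",
      if (any(x$peaks$substituted)) " + inflection substitution(s)", "\n",
      sep = "")
  cat("peaks:\n"); print(x$peaks)
  cat("troughs:\n"); print(x$troughs)
  invisible(x)
}

#' Coarticulation score
#'
#' 100 times the ratio of the mean of the first and third trough heights to
#' the mean of the (effective) peak heights. The second trough -- the
#' reversal at C, typically zero -- is excluded. Substituted inflection
#' heights enter both numerator and denominator. 0 means fully segmented
#' (complete stops at B and D); values near 100 mean fully blended movement.
#'
#' @param ps A [find_peak_structure()] result.
#' @return Score in \[0, 100\].
#' @export
coarticulation_score <- function(ps) {
  pk <- ps$peaks$height
  t1 <- ps$troughs$height[ps$troughs$ordinal == 1L]
  t3 <- ps$troughs$height[ps$troughs$ordinal == 3L]
  if (!length(t1) || !length(t3)) {
    stop("peak structure lacks trough 1 or 3: score undefined", call. = FALSE)
  }
  mp <- mean(pk)
  if (mp <= 0) stop("mean peak height is zero: score undefined", call. = FALSE)
  100 * mean(c(t1, t3)) / mp
}

#' Count qualifying velocity peaks
#'
#' Number of local maxima of the windowed tangential velocity with
#' topographic prominence of at least `prominence_frac` of the profile
#' maximum. Fewer peaks indicate greater coarticulation.
#'
#' @inheritParams find_peak_structure
#' @return Integer peak count.
#' @export
count_velocity_peaks <- function(vp, prominence_frac = 0.05) {
  length(qualifying_peaks(vp$v, prominence_frac))
}

# distance from points (px, py) to segment a-b
point_segment_dist <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  s <- ((px - a[1]) * abx + (py - a[2]) * aby) / len2
  s <- pmin(pmax(s, 0), 1)
  sqrt((px - (a[1] + s * abx))^2 + (py - (a[2] + s * aby))^2)
}

#' Path offset (curvature proxy)
#'
#' Mean distance from the trajectory samples to the nearest of the four
#' straight segments joining the targets in order (A-B, B-C, C-D, D-A).
#' Rises as coarticulated movements cut corners and curve away from the
#' straight paths.
#'
#' @param positions Tibble with `x`, `y` (windowed trajectory samples, cm).
#' @param layout A [target_layout()].
#' @return Mean offset in cm.
#' @export
path_offset <- function(positions, layout) {
  ctr <- target_centers(layout, close = TRUE)
  d <- sapply(seq_len(nrow(ctr) - 1L), function(i) {
    point_segment_dist(positions$x, positions$y, ctr[i, ], ctr[i + 1L, ])
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  mean(apply(d, 1, min))
}

# closest approach (cm) of the sampled polyline to a point
polyline_min_dist <- function(positions, point) {
  x <- positions$x; y <- positions$y
  n <- length(x)
  if (n == 1L) return(sqrt((x - point[1])^2 + (y - point[2])^2))
  ax <- x[-n]; ay <- y[-n]; bx <- x[-1]; by <- y[-1]
  abx <- bx - ax; aby <- by - ay
  len2 <- pmax(abx^2 + aby^2, 1e-300)
  s <- ((point[1] - ax) * abx + (point[2] - ay) * aby) / len2
  s <- pmin(pmax(s, 0), 1)
  min(sqrt((point[1] - (ax + s * abx))^2 + (point[2] - (ay + s * aby))^2))
}

#' Spatial error
#'
#' For each of the four targets, the distance from the target's disc edge to
#' the trajectory's closest approach (zero if the trajectory enters the
#' disc), summed over targets. A trajectory that passes through all four
#' discs scores zero.
#'
#' @param positions Tibble with `x`, `y` (windowed trajectory samples, cm).
#' @param layout A [target_layout()].
#' @return Summed miss distance in mm.
#' @export
spatial_error <- function(positions, layout) {
  ctr <- target_centers(layout)
  r <- target_radius_cm(layout)
  miss_cm <- vapply(rownames(ctr), function(lb) {
    max(polyline_min_dist(positions, ctr[lb, ]) - r, 0)
  }, numeric(1))
  sum(miss_cm) * 10
}

#' Normalize movement duration to percent improvement
#'
#' 100 * (baseline - value) / baseline: positive = faster than the subject's
#' own pre-test baseline.
#'
#' @param value Duration(s) (s).
#' @param baseline Pre-test baseline duration (s), > 0.
#' @return Percent improvement.
#' @export
normalize_duration <- function(value, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive", call. = FALSE)
  100 * (baseline - value) / baseline
}

#' Normalize a coarticulation score by baseline subtraction
#'
#' Plain difference (no division: baseline scores are often near zero).
#'
#' @param value Score(s).
#' @param baseline Pre-test baseline score.
#' @return Score difference.
#' @export
normalize_score <- function(value, baseline) value - baseline

#' Compute all trial-level measures for a trial set
#'
#' Runs the full per-trial pipeline: continuity screening, fixed-knot spline
#' smoothing, tangential velocity, onset/offset segmentation, and the four
#' outcome measures. Trials that fail screening or segmentation are flagged
#' (`excluded`, `reason`) with `NA` measures.
#'
#' @param tset A [trial_set()] (or nested trials tibble with a `samples`
#'   list-column plus a `layout` argument).
#' @param layout Layout override; defaults to the trial set's layout. May be
#'   a function of session name returning a layout, for protocols in which
#'   sessions use transformed layouts (mirror/scaled transfers).
#' @param knot_every,onset_frac,peak_frac,prominence_frac,max_gap_samples
#'   Pipeline tuning parameters (see the corresponding functions).
#' @return Tibble with one row per trial: identity columns, `duration` (s),
#'   `coart_score`, `n_peaks`, `path_offset` (cm), `spatial_error` (mm),
#'   `v_peak` (cm/s), `residual_rms` (cm), `excluded`, `reason`.
#' @export
analyze_trials <- function(tset, layout = NULL, knot_every = 6,
                           onset_frac = 0.05, peak_frac = 0.35,
                           prominence_frac = 0.05, max_gap_samples = 3) {
  if (inherits(tset, "trial_set")) {
    trials <- tset$trials
    rate <- tset$sample_rate_hz
    if (is.null(layout)) layout <- tset$layout
  } else {
    trials <- tset
    rate <- 160
    if (is.null(layout)) layout <- default_layout()
  }
  layout_for <- if (is.function(layout)) layout else function(session) layout

  na_row <- list(
    duration = NA_real_, coart_score = NA_real_, n_peaks = NA_integer_,
    path_offset = NA_real_, spatial_error = NA_real_, v_peak = NA_real_,
    residual_rms = NA_real_, excluded = TRUE, reason = NA_character_
  )
  one <- function(samples, session) {
    excl <- exclude_trial(samples, rate, max_gap_samples)
    if (excl$excluded) {
      na_row$reason <- excl$reason
      return(na_row)
    }
    lay <- layout_for(session)
    tryCatch({
      st <- smooth_trajectory(samples, knot_every)
      vp <- tangential_velocity(st)
      win <- detect_onset_offset(vp, onset_frac, peak_frac, prominence_frac)
      wvp <- window_profile(vp, win)
      pos <- eval_trajectory(st, wvp$t)
      ps <- find_peak_structure(wvp, positions = pos, layout = lay,
                                prominence_frac = prominence_frac)
      list(
        duration = movement_duration(win),
        coart_score = coarticulation_score(ps),
        n_peaks = count_velocity_peaks(wvp, prominence_frac),
        path_offset = path_offset(pos, lay),
        spatial_error = spatial_error(pos, lay),
        v_peak = attr(wvp, "v_peak"),
        residual_rms = st$residual_rms,
        excluded = FALSE, reason = NA_character_
      )
    }, error = function(e) {
      na_row$reason <- conditionMessage(e)
      na_row
    })
  }

  res <- purrr::map2(trials$samples, trials$session, one)
  cols <- lapply(stats::setNames(names(na_row), names(na_row)), function(f) {
    unlist(lapply(res, `[[`, f), use.names = FALSE)
  })
  dplyr::bind_cols(
    trials[, c("subject_id", "group", "session", "block", "trial")],
    tibble::new_tibble(cols, nrow = length(res))
  )
}
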