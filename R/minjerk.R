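# Minimum-jerk submovement superposition.
#
# A point-to-point stroke is modeled as a straight-path minimum-jerk movement:
# displacement fraction s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5 on tau in [0,1],
# which satisfies zero velocity/acceleration at both ends and has peak speed
# (15/8) * D / T at tau = 1/2. Sequential strokes are superposed by vector
# summation of their displacements; "overlap" o is the fraction of the stroke
# duration by which the next stroke's onset precedes the previous one's end.

mj_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 + tau * (-15 + 6 * tau))
}

mj_sdot <- function(tau) {
  out <- numeric(length(tau))
  i <- tau > 0 & tau < 1
  ti <- tau[i]
  out[i] <- ti^2 * (30 + ti * (-60 + 30 * ti))
  out
}

#' Single minimum-jerk submovement
#'
#' @param start,end Numeric length-2 start/end positions (cm).
#' @param duration Stroke duration T (s).
#' @param onset Onset time (s).
#' @return A `submovement`: list with `start`, `end`, `onset`, `duration`.
#' @export
submovement <- function(start, end, duration, onset = 0) {
  stopifnot(length(start) == 2L, length(end) == 2L, duration > 0)
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 onset = onset, duration = duration),
            class = "submovement")
}

#' Sample a minimum-jerk segment
#'
#' Evaluates the straight-path minimum-jerk stroke on a regular time grid.
#'
#' @param sub A [submovement()].
#' @param dt Sampling interval (s), default 1/160.
#' @return Tibble with `t`, `x`, `y`, `vx`, `vy`, `v` (tangential speed).
#' @export
minjerk_segment <- function(sub, dt = 1 / 160) {
  stopifnot(dt > 0)
  tt <- seq(sub$onset, sub$onset + sub$duration, by = dt)
  if (tail(tt, 1) < sub$onset + sub$duration) {
    tt <- c(tt, sub$onset + sub$duration)
  }
  superpose_trajectory(list(sub), times = tt)
}

# Positions of a superposition at arbitrary times: p(t) = start_1 + sum_k
# (end_k - start_k) s(tau_k).  Velocities are the corresponding vector sums.
superpose_eval <- function(subs, times) {
  x <- rep(subs[[1]]$start[1], length(times))
  y <- rep(subs[[1]]$start[2], length(times))
  vx <- numeric(length(times)); vy <- numeric(length(times))
  for (sub in subs) {
    tau <- (times - sub$onset) / sub$duration
    s <- mj_s(tau)
    sd <- mj_sdot(tau) / sub$duration
    dx <- sub$end[1] - sub$start[1]
    dy <- sub$end[2] - sub$start[2]
    x <- x + dx * s
    y <- y + dy * s
    vx <- vx + dx * sd
    vy <- vy + dy * sd
  }
  list(x = x, y = y, vx = vx, vy = vy)
}

#' Superpose submovements into one trajectory
#'
#' Position is the vector sum of submovement displacements (taken from the
#' first submovement's start), velocity the vector sum of submovement
#' velocities.
#'
#' @param subs List of [submovement()]s.
#' @param dt Sampling interval (s). Ignored when `times` is given.
#' @param times Optional explicit sample times.
#' @return Tibble with `t`, `x`, `y`, `vx`, `vy`, `v`.
#' @export
superpose_trajectory <- function(subs, dt = 1 / 160, times = NULL) {
  if (is.null(times)) {
    t0 <- min(vapply(subs, `[[`, 0, "onset"))
    t1 <- max(vapply(subs, function(s) s$onset + s$duration, 0))
    times <- seq(t0, t1, by = dt)
    if (tail(times, 1) < t1) times <- c(times, t1)
  }
  p <- superpose_eval(subs, times)
  tibble::new_tibble(
    list(t = times, x = p$x, y = p$y, vx = p$vx, vy = p$vy,
         v = sqrt(p$vx^2 + p$vy^2)),
    nrow = length(times)
  )
}

# Chain of four strokes A -> B' -> C -> D' -> A.  Pairs (1,2) and (3,4) overlap
# by fraction `overlap` of the stroke duration; pair (2,3) is pinned to zero
# overlap because the reversal at C forces a full stop there.
chain_submovements <- function(layout_pts, overlap, t_sub = 0.5) {
  if (overlap < 0 || overlap > 0.55) {
    stop("`overlap` must lie in [0, 0.55]", call. = FALSE)
  }
  A <- layout_pts[["A"]]; Bp <- layout_pts[["B"]]
  C <- layout_pts[["C"]]; Dp <- layout_pts[["D"]]
  on2 <- (1 - overlap) * t_sub
  on3 <- on2 + t_sub                      # end of stroke 2: no overlap at C
  on4 <- on3 + (1 - overlap) * t_sub
  list(
    submovement(A, Bp, t_sub, 0),
    submovement(Bp, C, t_sub, on2),
    submovement(C, Dp, t_sub, on3),
    submovement(Dp, A, t_sub, on4)
  )
}

# Continuous-time closest approach of a superposed path to a point:
# iterative vectorized grid refinement plus a final parabolic step.
closest_approach <- function(subs, point, lower, upper, n_coarse = 61) {
  lo <- lower; hi <- upper; n <- n_coarse
  for (r in 1:3) {
    grid <- seq(lo, hi, length.out = n)
    p <- superpose_eval(subs, grid)
    d2 <- (p$x - point[1])^2 + (p$y - point[2])^2
    i <- which.min(d2)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(n, i + 1L)]
    n <- 25L
  }
  # parabolic refinement of d^2 around the bracketed minimum
  h <- grid[2] - grid[1]
  if (i > 1L && i < length(grid)) {
    y1 <- d2[i - 1L]; y2 <- d2[i]; y3 <- d2[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom > 1e-300) 0.5 * (y1 - y3) / denom else 0
    delta <- max(min(delta, 1), -1)
    t_star <- grid[i] + delta * h
    q <- superpose_eval(subs, t_star)
    d2_star <- (q$x - point[1])^2 + (q$y - point[2])^2
    if (d2_star < y2) return(list(dist = sqrt(d2_star), t = t_star))
  }
  list(dist = sqrt(d2[i]), t = grid[i])
}

#' Solve virtual via-points so the superposed path hits the targets
#'
#' With temporal overlap, the raw superposition of strokes aimed at the
#' physical targets cuts the corners at B and D. This routine finds virtual
#' intermediate targets B' and D' (the aim points of strokes 1 and 3) such
#' that the superposed path passes through the physical B and D centers, by
#' bounded derivative-free minimization (Nelder-Mead) of the squared
#' continuous-time closest-approach distances. The two half-problems are
#' decoupled: near B only strokes 1-2 are active, near D only strokes 3-4.
#'
#' @param layout A [target_layout()].
#' @param overlap Overlap fraction in \[0, 0.55\].
#' @param t_sub Common stroke duration (s), default 0.5.
#' @param tol Convergence tolerance on the squared miss distance (cm^2).
#' @param init Optional list with starting values `B`, `D` (used for warm
#'   starts when sweeping a grid).
#' @param max_restarts Jittered restarts allowed on non-convergence.
#' @param anchor_weight Weight of a small quadratic penalty `|via - target|^2`
#'   that selects, among the one-parameter family of via-points whose path
#'   grazes the target, the one nearest the physical target. Keeps the
#'   solution unique and the sweep smooth; small enough that the residual
#'   miss stays far below `tol`.
#' @return List with `B`, `D` (virtual via-points, cm), `residual` (max miss
#'   distance to the two targets, cm) and `converged`.
#' @export
solve_via_points <- function(layout, overlap, t_sub = 0.5, tol = 1e-6,
                             init = NULL, max_restarts = 5,
                             anchor_weight = 1e-4) {
  ctr <- target_centers(layout)
  A <- ctr["A", ]; B <- ctr["B", ]; C <- ctr["C", ]; D <- ctr["D", ]
  if (overlap == 0) {
    return(list(B = B, D = D, residual = 0, converged = TRUE))
  }

  solve_half <- function(p_start, p_target, p_end, start_par) {
    # strokes p_start -> via -> p_end, overlapped; hit p_target
    miss2 <- function(par) {
      subs <- list(
        submovement(p_start, par, t_sub, 0),
        submovement(par, p_end, t_sub, (1 - overlap) * t_sub)
      )
      closest_approach(subs, p_target, 0, (2 - overlap) * t_sub)$dist^2
    }
    obj <- function(par) {
      miss2(par) + anchor_weight * sum((par - p_target)^2)
    }
    # deterministic jitter directions for restarts
    jit <- rbind(c(0, 0), c(0.2, 0.1), c(-0.15, 0.2), c(0.1, -0.25),
                 c(-0.2, -0.1), c(0.3, 0.3))
    best <- NULL
    for (r in seq_len(min(max_restarts + 1L, nrow(jit)))) {
      o <- stats::optim(start_par + jit[r, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
      # polish: the anchored objective has a stiff (miss) and a soft
      # (anchor) direction; gradient-based refinement pins the position in
      # the soft direction far more tightly than Nelder-Mead alone
      o <- stats::optim(o$par, obj, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 200))
      o$miss2 <- miss2(o$par)
      if (is.null(best) || o$value < best$value) best <- o
      if (best$miss2 <= tol) break
    }
    best
  }

  initB <- if (is.null(init)) B else init$B
  initD <- if (is.null(init)) D else init$D
  solB <- solve_half(A, B, C, initB)
  solD <- solve_half(C, D, A, initD)
  residual <- sqrt(max(solB$miss2, solD$miss2))
  converged <- solB$miss2 <= tol && solD$miss2 <= tol
  if (!converged) {
    stop("via-point optimization did not converge at overlap ", overlap,
         " (residual ", signif(residual, 3), " cm)", call. = FALSE)
  }
  list(B = stats::setNames(solB$par, c("x", "y")),
       D = stats::setNames(solD$par, c("x", "y")),
       residual = residual, converged = converged)
}

#' Simulate one overlapped sequence trial
#'
#' Convenience wrapper: solve via-points for the given overlap, superpose the
#' four strokes, and sample the trajectory.
#'
#' @inheritParams solve_via_points
#' @param dt Sampling interval (s).
#' @param via Optional pre-solved via-points (list with `B`, `D`).
#' @return Tibble as from [superpose_trajectory()].
#' @export
simulate_sequence_trial <- function(layout, overlap, t_sub = 0.5, dt = 1 / 160,
                                    via = NULL) {
  ctr <- target_centers(layout)
  if (is.null(via)) via <- solve_via_points(layout, overlap, t_sub)
  pts <- list(A = ctr["A", ], B = via$B, C = ctr["C", ], D = via$D)
  subs <- chain_submovements(pts, overlap, t_sub)
  superpose_trajectory(subs, dt = dt)
}

#' Sweep the overlap grid (predicted score and curvature curves)
#'
#' Simulates `n` equally spaced overlap values from `o_min` to `o_max`. For
#' each overlap, virtual via-points are solved so the path crosses the targets
#' (warm-started from the previous grid point), the four strokes are
#' superposed, and the trial-level measures are computed: coarticulation
#' score, path offset (curvature proxy, cm), and the number of tangential
#' velocity peaks.
#'
#' @inheritParams solve_via_points
#' @param o_min,o_max Grid endpoints (overlap fractions).
#' @param n Number of grid points (>= 2), default 551.
#' @param dt Sampling interval (s).
#' @return A `simulation_curve`: tibble with columns `overlap`, `score`,
#'   `curvature_cm`, `n_peaks`, `residual_cm`, and attributes `layout`,
#'   `t_sub`, `via` (list of solved via-points).
#' @export
simulate_grid <- function(layout, o_min = 0, o_max = 0.55, n = 551,
                          t_sub = 0.5, dt = 1 / 160, tol = 1e-6) {
  stopifnot(n >= 2, o_min >= 0, o_max <= 0.55, o_min < o_max)
  grid <- seq(o_min, o_max, length.out = n)
  via <- NULL
  rows <- vector("list", n)
  vias <- vector("list", n)
  for (i in seq_along(grid)) {
    o <- grid[i]
    via <- solve_via_points(layout, o, t_sub, tol = tol,
                            init = if (o > 0) via else NULL)
    vias[[i]] <- via
    # the predicted curves are evaluated on a finer grid than the nominal
    # recording rate: the trajectory is closed-form, and at 1/160 s the
    # sampling phase drifts with overlap, adding discretization ripple
    # comparable to one grid step of the score curve
    traj <- simulate_sequence_trial(layout, o, t_sub, dt = dt / 4, via = via)
    vp <- velocity_profile(traj$t, traj$v)
    win <- detect_onset_offset(vp)
    wvp <- window_profile(vp, win)
    wxy <- traj[traj$t >= win$t_on & traj$t <= win$t_off, c("t", "x", "y")]
    ps <- find_peak_structure(wvp, positions = wxy, layout = layout)
    # curvature over a fixed number of exact evaluations inside the window,
    # so the sample-inclusion set cannot jitter with the window edges
    ctr <- target_centers(layout)
    pts <- list(A = ctr["A", ], B = via$B, C = ctr["C", ], D = via$D)
    subs <- chain_submovements(pts, o, t_sub)
    fixed <- superpose_trajectory(
      subs, times = seq(win$t_on, win$t_off, length.out = 512))
    rows[[i]] <- tibble::tibble(
      overlap = o,
      score = coarticulation_score(ps),
      curvature_cm = path_offset(fixed, layout),
      n_peaks = count_velocity_peaks(wvp),
      residual_cm = via$residual
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("simulation_curve", class(out)),
            layout = layout, t_sub = t_sub, via = vias)
}

#' Invert the simulated score curve to an overlap estimate
#'
#' Monotone linear interpolation of the overlap-vs-score relation from a
#' [simulate_grid()] sweep. Scores outside the simulated range are clamped to
#' the nearest endpoint with a warning.
#'
#' @param curve A `simulation_curve`.
#' @param observed_score Numeric vector of coarticulation scores.
#' @return Estimated overlap fraction(s).
#' @export
estimate_overlap <- function(curve, observed_score) {
  sc <- curve$score
  ov <- curve$overlap
  # enforce strictly increasing abscissa for interpolation
  keep <- c(TRUE, diff(cummax(sc)) > 0)
  sc <- cummax(sc)[keep]; ov <- ov[keep]
  out <- numeric(length(observed_score))
  below <- observed_score < min(sc)
  above <- observed_score > max(sc)
  if (any(below | above)) {
    warning("observed score outside simulated range; estimate clamped",
            call. = FALSE)
  }
  out[below] <- ov[1]
  out[above] <- ov[length(ov)]
  inr <- !(below | above)
  if (any(inr)) {
    out[inr] <- stats::approx(sc, ov, xout = observed_score[inr],
                              ties = "ordered")$y
  }
  out
}
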