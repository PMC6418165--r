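# Synthetic cohort: a full four-group experiment (pre-test, six training
# blocks, post-test on day 1; trained / mirror / scaled tests on day 2) with
# known generative parameters, produced from the minimum-jerk superposition
# engine plus sensor noise, target misses and recording gaps.

#' Default group generative profiles
#'
#' Encodes the assumed learning dynamics per group as overlap / duration /
#' miss schedules:
#' * `OG` (observation): submovement overlap steps from 0 to a plateau within
#'   the first 5 training trials, then drifts up block-by-block; movement
#'   duration drops ~27% at training onset (2.00 s -> 1.38 s).
#' * `SOG` (slowed observation): same overlap dynamics (slightly steeper
#'   block drift), duration unchanged.
#' * `RMCG` / `DPTCG` (controls): overlap stays at 0, duration unchanged.
#' Observation groups get a transient target-miss bump at post-test that is
#' gone by day 2, and an accuracy cost in the mirror transfer; all groups
#' move faster in the scaled transfer (shorter distances, same target size).
#'
#' The overlap plateaus and block drifts are calibrated through the
#' simulated score-vs-overlap map of the default layout so that the measured
#' coarticulation score gains land near +20 (OG) / +25 (SOG) points with
#' block slopes near +0.7 / +1.0 points per block, the magnitudes typical of
#' observation-trained subjects on this task.
#'
#' @return Named list of group profiles (plain lists of schedule parameters).
#' @export
default_profiles <- function() {
  base <- list(
    o_step = 0, o_drift = 0, ramp_trials = 5,
    dur_pre = 2.00, dur_trained = 2.00, scaled_speedup = 0.88,
    miss_rate = c(pre = 0.10, train = 0.10, post = 0.10, day2 = 0.10,
                  mirror = 0.25, scaled = 0.12),
    miss_mag_mm = c(pre = 0.4, train = 0.4, post = 0.4, day2 = 0.4,
                    mirror = 0.6, scaled = 0.4),
    gap_rate = 0.033,
    n_test_trials = 60, n_train_trials = 30, n_train_blocks = 6,
    sd_o_subject = 0.03, sd_o_trial = 0.02,
    sd_dur_subject_frac = 0.05, sd_dur_trial_frac = 0.04,
    noise_sd_cm = 0.03
  )
  og <- utils::modifyList(base, list(
    o_step = 0.175, o_drift = 0.0042, dur_trained = 1.38,
    miss_rate = c(pre = 0.10, train = 0.25, post = 0.55, day2 = 0.10,
                  mirror = 0.60, scaled = 0.12),
    miss_mag_mm = c(pre = 0.4, train = 0.8, post = 1.2, day2 = 0.4,
                    mirror = 1.5, scaled = 0.4)
  ))
  sog <- utils::modifyList(og, list(o_step = 0.20, o_drift = 0.0055,
                                    dur_trained = 2.00))
  dptcg <- utils::modifyList(base, list(n_train_trials = 60))
  list(OG = c(og, group = "OG"),
       SOG = c(sog, group = "SOG"),
       RMCG = c(base, group = "RMCG"),
       DPTCG = c(dptcg, group = "DPTCG"))
}

# ramp weight: the step to plateau happens within the first `ramp_trials`
# trials of training block 1; 1 thereafter, 0 before training
ramp_weight <- function(profile, session, block, trial) {
  if (session == "pre") return(0)
  if (session != "train" || block > 1L) return(1)
  r <- profile$ramp_trials
  if (trial <= 2L) 0 else min(1, (trial - 2L) / (r - 2L))
}

# scheduled (noise-free) overlap and duration for one trial
schedule_trial <- function(profile, session, block, trial) {
  w <- ramp_weight(profile, session, block, trial)
  o_base <- if (session == "train") {
    profile$o_step + (block - 1L) * profile$o_drift
  } else if (session == "pre") 0 else {
    profile$o_step + (profile$n_train_blocks - 1L) * profile$o_drift
  }
  dur_base <- profile$dur_pre + w * (profile$dur_trained - profile$dur_pre)
  if (session == "scaled") dur_base <- dur_base * profile$scaled_speedup
  list(o = w * o_base, dur = dur_base)
}

# Via-point lookup: solve the optimization on a coarse overlap grid once per
# layout, then interpolate B'(o), D'(o) per trial (both vary smoothly).
build_via_table <- function(layout, t_sub = 0.5, o_max = 0.55, n = 23) {
  os <- seq(0, o_max, length.out = n)
  via <- NULL
  rows <- lapply(os, function(o) {
    via <<- solve_via_points(layout, o, t_sub,
                             init = if (o > 0) via else NULL)
    c(o, via$B, via$D)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("o", "bx", "by", "dx", "dy")
  m
}

interp_via <- function(tab, o) {
  list(
    B = c(x = stats::approx(tab[, "o"], tab[, "bx"], o)$y,
          y = stats::approx(tab[, "o"], tab[, "by"], o)$y),
    D = c(x = stats::approx(tab[, "o"], tab[, "dx"], o)$y,
          y = stats::approx(tab[, "o"], tab[, "dy"], o)$y)
  )
}

session_layout <- function(layout, session, scale_factor = 0.7) {
  switch(session,
         mirror = mirror_layout(layout),
         scaled = scale_layout(layout, scale_factor),
         layout)
}

# one synthetic trial: superposed strokes + dwell padding + sensor noise,
# optional via-point miss perturbation and recording-gap injection
synth_trial <- function(layout, via_tab, o, dur, profile, session,
                        dt = 1 / 160) {
  o <- min(max(o, 0), 0.55)
  t_sub <- dur / (4 - 2 * o - 0.12)   # 5% thresholds trim ~6% of a stroke/side
  via <- interp_via(via_tab, o)
  ctr <- target_centers(layout)
  miss <- stats::runif(1) < profile$miss_rate[[session]]
  miss_mag <- 0
  if (miss) {
    tgt <- if (stats::runif(1) < 0.5) "B" else "D"
    miss_mag <- profile$miss_mag_mm[[session]] *
      (0.5 + stats::rexp(1, rate = 2))
    centroid <- colMeans(ctr)
    u <- ctr[tgt, ] - centroid
    u <- u / sqrt(sum(u^2))
    shift <- (target_radius_cm(layout) + miss_mag / 10) * 1.5
    via[[tgt]] <- via[[tgt]] + shift * u
  }
  pts <- list(A = ctr["A", ], B = via$B, C = ctr["C", ], D = via$D)
  subs <- chain_submovements(pts, o, t_sub)
  core <- superpose_trajectory(subs, dt = dt)
  pre_t <- seq(-0.30, -dt, by = dt)
  post_t <- seq(max(core$t) + dt, max(core$t) + 0.55, by = dt)
  A <- ctr["A", ]
  t_all <- c(pre_t, core$t, post_t) + 0.30
  x <- c(rep(A[1], length(pre_t)), core$x, rep(A[1], length(post_t)))
  y <- c(rep(A[2], length(pre_t)), core$y, rep(A[2], length(post_t)))
  x <- x + stats::rnorm(length(x), 0, profile$noise_sd_cm)
  y <- y + stats::rnorm(length(y), 0, profile$noise_sd_cm)
  gap <- stats::runif(1) < profile$gap_rate
  if (gap) {
    g <- sample(5:12, 1)
    i0 <- sample(seq(length(pre_t) + 5L, length(pre_t) + nrow(core) - g - 5L), 1)
    keep <- setdiff(seq_along(t_all), i0:(i0 + g - 1L))
    t_all <- t_all[keep]; x <- x[keep]; y <- y[keep]
  }
  list(samples = tibble::new_tibble(list(t = t_all, x = x, y = y),
                                    nrow = length(t_all)),
       miss = miss, miss_mag_mm = miss_mag, gap = gap, o = o, t_sub = t_sub)
}

session_plan <- function(profile) {
  tests <- c("pre", "post", "day2", "mirror", "scaled")
  plan <- dplyr::bind_rows(
    tibble::tibble(session = "pre", block = 1L,
                   trial = seq_len(profile$n_test_trials)),
    tidyr::expand_grid(session = "train",
                       block = seq_len(profile$n_train_blocks),
                       trial = seq_len(profile$n_train_trials)),
    dplyr::bind_rows(lapply(setdiff(tests, "pre"), function(s) {
      tibble::tibble(session = s, block = 1L,
                     trial = seq_len(profile$n_test_trials))
    }))
  )
  ord <- c("pre", "train", "post", "day2", "mirror", "scaled")
  plan[order(match(plan$session, ord), plan$block, plan$trial), ]
}

#' Generate one synthetic subject
#'
#' Draws per-trial overlap and duration from the group schedule with
#' between-subject and trial-to-trial Gaussian jitter, builds each trial from
#' the minimum-jerk superposition engine (via-points interpolated from a
#' pre-solved table), injects target misses and recording gaps at the
#' session rates, and adds positional sensor noise.
#'
#' @param profile One entry of [default_profiles()].
#' @param subject_id Subject identifier string.
#' @param seed Integer seed for this subject (sets the RNG).
#' @param layout Base [target_layout()].
#' @param via_tables Optional named list of via-point tables for the
#'   trained / mirror / scaled layouts (built if missing).
#' @return List with `trials` (nested tibble) and `truth` (tibble of
#'   generative parameters per trial).
#' @export
generate_subject <- function(profile, subject_id, seed,
                             layout = default_layout(), via_tables = NULL) {
  set.seed(seed)
  if (is.null(via_tables)) {
    via_tables <- list(
      trained = build_via_table(layout),
      mirror = build_via_table(mirror_layout(layout)),
      scaled = build_via_table(scale_layout(layout, 0.7))
    )
  }
  plan <- session_plan(profile)
  subj_o_jit <- stats::rnorm(1, 0, profile$sd_o_subject)
  subj_dur_fac <- exp(stats::rnorm(1, 0, profile$sd_dur_subject_frac))

  n <- nrow(plan)
  samples <- vector("list", n)
  o_true_v <- dur_v <- mag_v <- numeric(n)
  miss_v <- gap_v <- logical(n)
  layouts <- list(trained = layout, mirror = mirror_layout(layout),
                  scaled = scale_layout(layout, 0.7))
  for (i in seq_len(n)) {
    ses <- plan$session[i]; blk <- plan$block[i]; tri <- plan$trial[i]
    sch <- schedule_trial(profile, ses, blk, tri)
    w <- ramp_weight(profile, ses, blk, tri)
    o_true <- sch$o + w * subj_o_jit + stats::rnorm(1, 0, profile$sd_o_trial)
    o_true <- min(max(o_true, 0), 0.55)
    dur <- sch$dur * subj_dur_fac *
      exp(stats::rnorm(1, 0, profile$sd_dur_trial_frac))
    key <- switch(ses, mirror = "mirror", scaled = "scaled", "trained")
    tr <- synth_trial(layouts[[key]], via_tables[[key]], o_true, dur,
                      profile, ses)
    samples[[i]] <- tr$samples
    o_true_v[i] <- tr$o; dur_v[i] <- dur
    miss_v[i] <- tr$miss; mag_v[i] <- tr$miss_mag_mm; gap_v[i] <- tr$gap
  }
  id_cols <- list(subject_id = rep(subject_id, n),
                  group = rep(profile$group, n),
                  session = plan$session, block = plan$block,
                  trial = plan$trial)
  list(
    trials = tibble::new_tibble(c(id_cols, list(samples = samples)), nrow = n),
    truth = tibble::new_tibble(
      c(id_cols, list(o_true = o_true_v, dur_target = dur_v, miss = miss_v,
                      miss_mag_mm = mag_v, gap = gap_v)),
      nrow = n
    )
  )
}

#' Generate a full synthetic cohort
#'
#' Four groups (OG, SOG, RMCG, DPTCG) of `n_per_group` subjects each run
#' through the full protocol: day 1 pre-test, six training blocks and
#' post-test; day 2 trained, mirror and scaled tests (transfer layouts built
#' with [mirror_layout()] / [scale_layout()]). Per-subject seeds are derived
#' deterministically from `master_seed`, so regeneration is bit-identical.
#'
#' @param n_per_group Subjects per group (default 15).
#' @param master_seed Integer master seed.
#' @param layout Base [target_layout()].
#' @param profiles Group profiles, as [default_profiles()].
#' @return A `cohort_dataset`: list with `tset` (a [trial_set()]), `truth`
#'   (generative parameters per trial), `profiles` and `master_seed`.
#' @export
generate_cohort <- function(n_per_group = 15, master_seed = 1,
                            layout = default_layout(),
                            profiles = default_profiles()) {
  stopifnot(n_per_group >= 2)
  set.seed(master_seed)
  n_subj <- n_per_group * length(profiles)
  seeds <- sample.int(.Machine$integer.max, n_subj)
  via_tables <- list(
    trained = build_via_table(layout),
    mirror = build_via_table(mirror_layout(layout)),
    scaled = build_via_table(scale_layout(layout, 0.7))
  )
  k <- 0L
  all <- vector("list", n_subj)
  for (g in names(profiles)) {
    for (s in seq_len(n_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s%02d", g, s)
      all[[k]] <- generate_subject(profiles[[g]], sid, seeds[k],
                                   layout, via_tables)
    }
  }
  trials <- dplyr::bind_rows(lapply(all, `[[`, "trials"))
  truth <- dplyr::bind_rows(lapply(all, `[[`, "truth"))
  tset <- trial_set(trials, layout = layout, sample_rate_hz = 160,
                    provenance = sprintf("synthetic cohort, master seed %d",
                                         master_seed))
  structure(list(tset = tset, truth = truth, profiles = profiles,
                 master_seed = master_seed),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> master seed ", x$master_seed, "; ",
      dplyr::n_distinct(x$tset$trials$subject_id), " subjects, ",
      nrow(x$tset$trials), " trials\n", sep = "")
  invisible(x)
}
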