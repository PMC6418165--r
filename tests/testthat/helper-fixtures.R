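# Fixtures built in code: clean profiles, noiseless minimum-jerk trials,
# and small trial sets.

# triangular velocity bump of given height over [t0, t0 + width], zero outside
triangle_profile <- function(t, t0, width, height) {
  tau <- (t - t0) / width
  h <- pmax(0, 1 - abs(2 * tau - 1)) * height
  h
}

# profile made of `k` separated triangular bumps with zero rests between
multi_bump_profile <- function(k = 4, heights = rep(10, k), dt = 1 / 160,
                               width = 0.4, rest = 0.2) {
  t_end <- k * width + (k + 1) * rest
  t <- seq(0, t_end, by = dt)
  v <- numeric(length(t))
  for (i in seq_len(k)) {
    t0 <- rest * i + width * (i - 1)
    v <- v + triangle_profile(t, t0, width, heights[i])
  }
  velocity_profile(t, v)
}

# noiseless single minimum-jerk stroke as a trial-like sample table,
# padded with rest at both ends
minjerk_trial_samples <- function(start = c(0, 0), end = c(10, 0),
                                  duration = 1, dt = 1 / 160,
                                  pad = 0.25) {
  seg <- minjerk_segment(submovement(start, end, duration), dt = dt)
  pre <- seq(-pad, -dt, by = dt)
  post <- seq(max(seg$t) + dt, max(seg$t) + pad, by = dt)
  tibble::tibble(
    t = c(pre, seg$t, post) + pad,
    x = c(rep(start[1], length(pre)), seg$x, rep(end[1], length(post))),
    y = c(rep(start[2], length(pre)), seg$y, rep(end[2], length(post)))
  )
}

# small well-formed trial set (2 trials)
make_tiny_trial_set <- function() {
  s1 <- minjerk_trial_samples()
  s2 <- minjerk_trial_samples(end = c(8, 4), duration = 0.8)
  trials <- tibble::tibble(
    subject_id = c("s01", "s01"), group = c("OG", "OG"),
    session = c("pre", "pre"), block = c(1L, 1L), trial = c(1L, 2L),
    samples = list(s1, s2)
  )
  trial_set(trials, layout = default_layout(), sample_rate_hz = 160,
            provenance = "fixture")
}
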