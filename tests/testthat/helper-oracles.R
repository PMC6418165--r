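# Independent brute-force oracles, written as plain scans so they stay
# independent of the package's implementations.

# all strict local maxima of v by direct neighbour comparison
oracle_local_maxima <- function(v) {
  out <- integer(0)
  for (i in 2:(length(v) - 1)) {
    if (v[i] > v[i - 1] && v[i] > v[i + 1]) out <- c(out, i)
  }
  out
}

# prominence by walking out from the peak until a higher sample is met
oracle_prominence <- function(v, i) {
  h <- v[i]
  lmin <- h
  j <- i - 1
  while (j >= 1 && v[j] <= h) { lmin <- min(lmin, v[j]); j <- j - 1 }
  if (j < 1) lmin <- min(v[1:i])
  rmin <- h
  j <- i + 1
  while (j <= length(v) && v[j] <= h) { rmin <- min(rmin, v[j]); j <- j + 1 }
  if (j > length(v)) rmin <- min(v[i:length(v)])
  h - max(lmin, rmin)
}

# qualifying peaks: local maxima with prominence >= frac * max(v)
oracle_peaks <- function(v, frac = 0.05) {
  idx <- oracle_local_maxima(v)
  idx[vapply(idx, function(i) oracle_prominence(v, i), 0) >= frac * max(v)]
}

# onset/offset by linear threshold scan (offset: last supra-threshold run
# lasting at least min_above_s)
oracle_window <- function(t, v, onset_frac = 0.05, peak_frac = 0.35,
                          prom_frac = 0.05, min_above_s = 0.05) {
  vp <- max(v)
  pks <- oracle_peaks(v, prom_frac)
  pks <- pks[v[pks] > peak_frac * vp]
  first_pk <- pks[1]
  i_on <- NA
  for (i in 1:first_pk) if (v[i] < onset_frac * vp) i_on <- i
  i_off <- NA
  run_start <- NA
  for (i in seq_along(v)) {
    if (v[i] > onset_frac * vp) {
      if (is.na(run_start)) run_start <- i
    } else {
      if (!is.na(run_start) && t[i - 1] - t[run_start] >= min_above_s) {
        i_off <- i - 1
      }
      run_start <- NA
    }
  }
  if (!is.na(run_start) && t[length(t)] - t[run_start] >= min_above_s) {
    i_off <- length(t)
  }
  if (is.na(i_off)) i_off <- max(which(v > onset_frac * vp))
  list(t_on = t[i_on], t_off = t[i_off])
}

# 4 largest qualifying peaks in time order + interior global-minimum troughs
oracle_peak_trough <- function(v, frac = 0.05) {
  pks <- oracle_peaks(v, frac)
  if (length(pks) > 4) {
    hs <- v[pks]
    keep <- order(-hs, pks)[1:4]
    pks <- sort(pks[keep])
  }
  trs <- integer(0)
  if (length(pks) >= 2) {
    for (j in 1:(length(pks) - 1)) {
      span <- (pks[j] + 1):(pks[j + 1] - 1)
      trs <- c(trs, span[which.min(v[span])])
    }
  }
  list(peaks = pks, troughs = trs)
}

# mean arc-to-chord distance of a semicircular detour, by quadrature
oracle_semicircle_mean_offset <- function(r, n = 20000) {
  theta <- seq(0, pi, length.out = n)
  mean(r * sin(theta))
}
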