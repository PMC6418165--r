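# closed-form split-plot sums of squares for a balanced design (oracle)
oracle_mixed_f <- function(d) {
  # d: subject, grp, w, y; balanced
  gm <- mean(d$y)
  a <- length(unique(d$grp)); b <- length(unique(d$w))
  n <- length(unique(d$subject)) / a
  gmean <- tapply(d$y, d$grp, mean)
  wmean <- tapply(d$y, d$w, mean)
  cmean <- tapply(d$y, list(d$grp, d$w), mean)
  smean <- tapply(d$y, d$subject, mean)
  sgrp <- tapply(d$grp, d$subject, function(g) g[1])
  ssa <- n * b * sum((gmean - gm)^2)
  ss_subj <- b * sum((smean - gmean[sgrp])^2)
  ssb <- a * n * sum((wmean - gm)^2)
  ssab <- n * sum((sweep(sweep(cmean, 1, gmean), 2, wmean) + gm)^2)
  sse <- sum((d$y - cmean[cbind(d$grp, d$w)] - smean[d$subject] +
                gmean[sgrp[d$subject]])^2)
  dfa <- a - 1; dfs <- a * (n - 1); dfb <- b - 1
  dfab <- (a - 1) * (b - 1); dfe <- a * (n - 1) * (b - 1)
  list(
    F_between = (ssa / dfa) / (ss_subj / dfs),
    F_within = (ssb / dfb) / (sse / dfe),
    F_inter = (ssab / dfab) / (sse / dfe),
    df = c(dfa, dfs, dfb, dfab, dfe)
  )
}

make_summary_toy <- function(n = 6, groups = c("g1", "g2"),
                             sessions = c("pre", "post"), seed = 5,
                             effect = 0) {
  withr::local_seed(seed)
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:(n * length(groups))),
                          session = sessions)
  d$group <- groups[(match(d$subject_id, unique(d$subject_id)) - 1L) %%
                      length(groups) + 1L]
  d$y <- rnorm(nrow(d)) +
    effect * (d$group == groups[1]) * (d$session == sessions[length(sessions)])
  d
}

test_that("summaries use the per-measure conventions and are robust", {
  m <- tibble::tibble(
    subject_id = "s1", group = "OG", session = "pre", block = 1L,
    trial = 1:5,
    duration = c(1, 1, 1, 1, 100),       # extreme outlier
    coart_score = c(10, 20, 30, 40, 50),
    n_peaks = c(4L, 4L, 4L, 3L, 4L),
    path_offset = rep(0.2, 5),
    spatial_error = c(0, 0, 0, 0, 10),
    excluded = FALSE, reason = NA_character_
  )
  s <- summarize_measures(m)
  expect_equal(nrow(s), 1L)
  expect_equal(s$duration, 1)            # median kills the outlier
  expect_equal(s$spatial_error, 0)
  expect_equal(s$coart_score, 30)        # mean
  expect_equal(s$n_peaks, 3.8)
  # identical trials reproduce the trial values; excluded trials are dropped
  m2 <- m; m2$duration <- 2; m2$excluded <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  s2 <- summarize_measures(m2)
  expect_equal(s2$duration, 2)
  expect_equal(s2$n_trials, 4L)
  # normalized columns use the subject's own pre-test baseline
  m3 <- dplyr::bind_rows(m, dplyr::mutate(m, session = "post",
                                          duration = .data$duration / 2,
                                          coart_score = .data$coart_score + 12))
  s3 <- summarize_measures(m3)
  expect_equal(s3$duration_norm[s3$session == "post"], 50)
  expect_equal(s3$coart_norm[s3$session == "post"], 12)
  expect_equal(s3$duration_norm[s3$session == "pre"], 0)
  # 5-trial binning
  m4 <- dplyr::mutate(m, trial = 6:10)
  s4 <- summarize_measures(dplyr::bind_rows(m, m4), bin_width = 5)
  expect_equal(sort(unique(s4$bin)), c(1L, 2L))
  # permutation invariance within a block
  s5 <- summarize_measures(m[sample(5), ])
  expect_equal(s5$coart_score, s$coart_score)
})

test_that("mixed ANOVA matches closed-form split-plot sums of squares", {
  d <- make_summary_toy(n = 6, effect = 1.2)
  fit <- mixed_anova(d, "y")
  orc <- oracle_mixed_f(tibble::tibble(subject = d$subject_id, grp = d$group,
                                       w = d$session, y = d$y))
  tab <- tidy(fit)
  expect_equal(tab$statistic[tab$effect == "between"], orc$F_between,
               tolerance = 1e-9)
  expect_equal(tab$statistic[tab$effect == "within"], orc$F_within,
               tolerance = 1e-9)
  expect_equal(tab$statistic[tab$effect == "interaction"], orc$F_inter,
               tolerance = 1e-9)
  expect_equal(tab$df1[tab$effect == "interaction"], orc$df[4])
  expect_equal(tab$df2[tab$effect == "interaction"], orc$df[5])
  expect_equal(glance(fit)$n_subjects, 12L)
})

test_that("identical group response multisets give zero interaction F", {
  # both groups contain the same set of subject response vectors
  base <- matrix(c(1, 2, 3, 2, 2, 4, 0, 1, 2, 3, 3, 5), ncol = 3, byrow = TRUE)
  d <- purrr::map_dfr(1:2, function(g) {
    purrr::map_dfr(1:4, function(i) {
      tibble::tibble(subject_id = sprintf("g%ds%d", g, i),
                     group = paste0("g", g),
                     session = c("a", "b", "c"), y = base[i, ])
    })
  })
  tab <- tidy(mixed_anova(d, "y"))
  expect_equal(tab$statistic[tab$effect == "interaction"], 0,
               tolerance = 1e-12)
  expect_equal(tab$statistic[tab$effect == "between"], 0, tolerance = 1e-12)
})

test_that("Greenhouse-Geisser correction engages with 3+ within levels", {
  d <- make_summary_toy(n = 8, sessions = c("a", "b", "c"), seed = 17)
  tab <- tidy(mixed_anova(d, "y"))
  eps <- tab$gg_epsilon[tab$effect == "within"]
  expect_false(is.na(eps))
  expect_gt(eps, 0); expect_lte(eps, 1 + 1e-12)
  expect_false(is.na(tab$p_gg[tab$effect == "interaction"]))
  # with 2 levels sphericity is moot and no correction is reported
  d2 <- make_summary_toy(n = 8, sessions = c("a", "b"), seed = 18)
  tab2 <- tidy(mixed_anova(d2, "y"))
  expect_true(all(is.na(tab2$p_gg)))
  expect_equal(tab2$p_reported, tab2$p_value)
})

test_that("mixed ANOVA validates its design", {
  d <- make_summary_toy(n = 1)
  expect_error(mixed_anova(d, "y"), "at least 2 subjects")
})

test_that("slope analysis recovers exact and null slopes", {
  mk <- function(slopes, group) {
    purrr::map_dfr(seq_along(slopes), function(i) {
      tibble::tibble(subject_id = sprintf("%s%02d", group, i), group = group,
                     block = 1:6, y = 10 + slopes[i] * (1:6))
    })
  }
  d <- dplyr::bind_rows(mk(rep(0.73, 8), "OG"), mk(rep(0, 8), "RMCG"))
  # add distinct per-subject intercept noise but keep slopes exact
  res <- slope_analysis(d, "y", alternative = "greater")
  expect_equal(res$slopes$slope[res$slopes$group == "OG"], rep(0.73, 8),
               tolerance = 1e-12)
  tab <- tidy(res)
  expect_equal(tab$mean_slope[tab$group == "OG"], 0.73, tolerance = 1e-12)
  # flat series: slope 0, t = 0, p = 1 under the degenerate-variance rule
  expect_equal(tab$statistic[tab$group == "RMCG"], 0)
  expect_equal(tab$p_value[tab$group == "RMCG"], 1)
  # noisy positive slopes are detected one-tailed
  withr::local_seed(2)
  dn <- purrr::map_dfr(1:10, function(i) {
    tibble::tibble(subject_id = sprintf("s%02d", i), group = "OG",
                   block = 1:6, y = 0.7 * (1:6) + rnorm(6, 0, 0.5))
  })
  expect_lt(tidy(slope_analysis(dn, "y"))$p_value, 0.01)
  expect_error(slope_analysis(dn[dn$block < 3, ], "y"), "fewer than 3")
})

test_that("Friedman chi-square matches hand-computed rank arithmetic", {
  # 5 subjects x 3 conditions toy
  y <- matrix(c(1, 2, 3,
                2, 1, 3,
                1, 3, 2,
                1, 2, 3,
                2, 3, 1), ncol = 3, byrow = TRUE)
  d <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:5), each = 3),
    session = rep(c("a", "b", "c"), 5),
    spatial_error = as.vector(t(y))
  )
  res <- nonparametric_battery(d, design = "within", posthoc = FALSE)
  # hand: ranks within subject are the values themselves here
  rsum <- colSums(y)
  n <- 5; k <- 3
  chi2 <- 12 / (n * k * (k + 1)) * sum(rsum^2) - 3 * n * (k + 1)
  expect_equal(res$omnibus$statistic, chi2, tolerance = 1e-9)
  expect_equal(res$omnibus$df, 2)
  # identical columns: chi-square 0
  d0 <- d; d0$spatial_error <- rep(c(1, 1, 1), 5)
  res0 <- nonparametric_battery(d0, design = "within", posthoc = FALSE)
  expect_equal(res0$omnibus$statistic, 0)
})

test_that("between-group non-parametrics find no difference in identical groups", {
  d <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("g1", "g2"), each = 10),
    spatial_error = rep(0, 20)
  )
  res <- nonparametric_battery(d, design = "between")
  expect_false(isTRUE(res$omnibus$p_value < 0.05))
  expect_false(any(res$pairwise$p_adjusted < 0.05, na.rm = TRUE))
  # a genuine shift is detected
  d2 <- d; d2$spatial_error[d2$group == "g2"] <- rnorm(10, 5, 0.5)
  res2 <- nonparametric_battery(d2, design = "between")
  expect_lt(res2$omnibus$p_value, 0.01)
})

test_that("Bonferroni correction multiplies and caps", {
  withr::local_seed(9)
  d <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:8),
                          session = c("a", "b", "c", "d"))
  d$y <- rnorm(nrow(d))
  ph <- posthoc_pairwise(d, "y", "session")
  expect_equal(nrow(ph), 6L)
  expect_equal(ph$p_adjusted, pmin(1, ph$p_raw * 6))
  ph2 <- posthoc_pairwise(d, "y", "session", levels = c("a", "b"))
  expect_equal(nrow(ph2), 1L)
  expect_equal(ph2$p_adjusted, ph2$p_raw)
})

test_that("transfer battery flags missing sessions and null effects", {
  withr::local_seed(13)
  base <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:12),
                             session = c("day2", "mirror", "scaled"))
  base$group <- ifelse(match(base$subject_id, unique(base$subject_id)) %% 2 ==
                         0, "g1", "g2")
  subj_eff <- rnorm(12)[match(base$subject_id, unique(base$subject_id))]
  base <- dplyr::mutate(base,
                        block = 1L,
                        duration_norm = subj_eff + rnorm(dplyr::n(), 0, .1),
                        coart_norm = subj_eff + rnorm(dplyr::n(), 0, .1),
                        path_offset = abs(subj_eff) + .2,
                        n_peaks = 4,
                        spatial_error = abs(rnorm(dplyr::n(), 0, .1)))
  res <- transfer_analysis(base)
  expect_named(res, c("duration", "coart", "path_offset", "n_peaks",
                      "spatial_error"))
  # identical day-2 sessions (up to noise): no transfer-type effect
  tab <- tidy(res$duration)
  expect_gt(tab$p_reported[tab$effect == "within"], 0.05)
  expect_error(transfer_analysis(base[base$session != "mirror", ]),
               "missing transfer session")
})
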