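# Group-level statistics: per-block summaries, mixed-design ANOVA with
# Greenhouse-Geisser correction, per-subject regression slopes, and the
# non-parametric battery (Friedman / Wilcoxon / Kruskal-Wallis /
# Mann-Whitney) used for spatial error.

#' Summarize trial measures per subject, session and block
#'
#' Collapses trial-level measures to one row per (subject, group, session,
#' block) -- or per 5-trial bin when `bin_width` is set -- using the
#' per-measure conventions: median for duration and spatial error, mean for
#' coarticulation score, path offset and peak count. Excluded trials are
#' dropped first. Normalized columns use each subject's own pre-test
#' baseline: percent improvement for duration
#' (`100 * (baseline - value) / baseline`), baseline subtraction for the
#' coarticulation score, percent change for path offset.
#'
#' @param measures Trial-level tibble from [analyze_trials()].
#' @param bin_width Optional bin width in trials (e.g. 5 for 5-trial bins);
#'   adds a `bin` key column.
#' @return Summary tibble keyed by subject/group/session/block (and `bin`),
#'   with `duration`, `spatial_error`, `coart_score`, `path_offset`,
#'   `n_peaks`, `n_trials`, and `duration_norm`, `coart_norm`,
#'   `path_offset_norm` where a pre-test baseline exists.
#' @export
summarize_measures <- function(measures, bin_width = NULL) {
  keep <- dplyr::filter(measures, !.data$excluded)
  keys <- c("subject_id", "group", "session", "block")
  if (!is.null(bin_width)) {
    keep <- dplyr::mutate(keep,
                          bin = (.data$trial - 1L) %/% as.integer(bin_width) + 1L)
    keys <- c(keys, "bin")
  }
  out <- keep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      duration = stats::median(.data$duration),
      spatial_error = stats::median(.data$spatial_error),
      coart_score = mean(.data$coart_score),
      path_offset = mean(.data$path_offset),
      n_peaks = mean(.data$n_peaks),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  base <- out |>
    dplyr::filter(.data$session == "pre") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      dur_base = mean(.data$duration),
      coart_base = mean(.data$coart_score),
      po_base = mean(.data$path_offset),
      .groups = "drop"
    )
  out <- dplyr::left_join(out, base, by = "subject_id")
  out <- dplyr::mutate(
    out,
    duration_norm = ifelse(!is.na(.data$dur_base) & .data$dur_base > 0,
                           normalize_duration(.data$duration, .data$dur_base),
                           NA_real_),
    coart_norm = normalize_score(.data$coart_score, .data$coart_base),
    path_offset_norm = ifelse(!is.na(.data$po_base) & .data$po_base > 0,
                              100 * (.data$path_offset - .data$po_base) /
                                .data$po_base,
                              NA_real_)
  )
  dplyr::select(out, -"dur_base", -"coart_base", -"po_base")
}

#' Mixed-design ANOVA (between-subjects group, within-subjects factor)
#'
#' Classic split-plot ANOVA via a multivariate linear model and
#' `car::Anova()` (type III). With three or more within-subject levels the
#' Greenhouse-Geisser correction is applied to the within and interaction
#' tests (reported alongside the uncorrected p). Subjects with missing cells
#' are dropped listwise; multiple rows per cell are averaged first.
#'
#' @param data Summary tibble (one row per subject x within level, or finer).
#' @param dv Name of the dependent variable column.
#' @param between Name of the between-subjects factor column (default
#'   `"group"`).
#' @param within Name of the within-subjects factor column (default
#'   `"session"`).
#' @param subject Name of the subject identifier column.
#' @param sphericity `"greenhouse-geisser"` (default) or `"none"`.
#' @return A `coart_anova` object; see [tidy()] for the effect table with
#'   columns effect, df1, df2, statistic, p_value and (when corrected)
#'   gg_epsilon, p_gg.
#' @export
mixed_anova <- function(data, dv, between = "group", within = "session",
                        subject = "subject_id",
                        sphericity = c("greenhouse-geisser", "none")) {
  sphericity <- match.arg(sphericity)
  d <- tibble::tibble(
    subject = as.character(data[[subject]]),
    grp = factor(data[[between]]),
    w = factor(data[[within]]),
    y = data[[dv]]
  )
  d <- d[stats::complete.cases(d), ]
  d <- d |>
    dplyr::group_by(.data$subject, .data$grp, .data$w) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  if (nlevels(droplevels(d$grp)) < 2 && nlevels(droplevels(d$w)) < 2) {
    stop("need at least 2 levels in a factor", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(d, names_from = "w", values_from = "y")
  wlev <- levels(d$w)
  wide <- wide[stats::complete.cases(wide[, wlev]), ]
  n_by_g <- table(droplevels(wide$grp))
  if (any(n_by_g < 2)) {
    stop("each group cell needs at least 2 subjects", call. = FALSE)
  }
  Y <- as.matrix(wide[, wlev])
  grp <- droplevels(wide$grp)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op), add = TRUE)
  mlm <- stats::lm(Y ~ grp)
  idata <- data.frame(w = factor(wlev, levels = wlev))
  aov_res <- car::Anova(mlm, idata = idata, idesign = ~w, type = 3)
  # car warns when the Huynh-Feldt epsilon exceeds 1; that path is not used
  s <- suppressWarnings(summary(aov_res, multivariate = FALSE))
  ut <- s$univariate.tests
  # columns: Sum Sq, num Df, Error SS, den Df, F value, Pr(>F)
  keep_rows <- rownames(ut) != "(Intercept)"
  eff_map <- c("grp" = "between", "w" = "within", "grp:w" = "interaction")
  tab <- tibble::tibble(
    effect = unname(eff_map[rownames(ut)[keep_rows]]),
    term = rownames(ut)[keep_rows],
    df1 = unname(ut[keep_rows, 2]),
    df2 = unname(ut[keep_rows, 4]),
    statistic = unname(ut[keep_rows, 5]),
    p_value = unname(ut[keep_rows, 6])
  )
  tab$gg_epsilon <- NA_real_
  tab$p_gg <- NA_real_
  if (sphericity == "greenhouse-geisser" && length(wlev) >= 3 &&
      !is.null(s$pval.adjustments) && nrow(s$pval.adjustments) > 0) {
    adj <- s$pval.adjustments
    for (r in rownames(adj)) {
      i <- which(tab$term == r)
      tab$gg_epsilon[i] <- adj[r, "GG eps"]
      tab$p_gg[i] <- adj[r, "Pr(>F[GG])"]
    }
  }
  tab$p_reported <- ifelse(is.na(tab$p_gg), tab$p_value, tab$p_gg)
  structure(
    list(table = dplyr::select(tab, -"term"), dv = dv, between = between,
         within = within, n_subjects = nrow(wide),
         within_levels = wlev, sphericity = sphericity,
         data = wide),
    class = "coart_anova"
  )
}

#' @export
print.coart_anova <- function(x, ...) {
  cat("Mixed-design ANOVA on `", x$dv, "` (", x$n_subjects, " subjects; ",
      x$between, " x ", x$within, ")\n", sep = "")
  print(as.data.frame(x$table), digits = 4)
  if (x$sphericity == "greenhouse-geisser" && any(!is.na(x$table$p_gg))) {
    cat("p_gg: Greenhouse-Geisser corrected\n")
  }
  invisible(x)
}

#' @rdname mixed_anova
#' @param x A `coart_anova` object.
#' @param ... Unused.
#' @export
tidy.coart_anova <- function(x, ...) x$table

#' @rdname mixed_anova
#' @export
glance.coart_anova <- function(x, ...) {
  tibble::tibble(dv = x$dv, n_subjects = x$n_subjects,
                 n_within_levels = length(x$within_levels),
                 sphericity = x$sphericity)
}

#' Per-subject regression slopes over training blocks
#'
#' Fits an ordinary least-squares slope of `dv` on block number for each
#' subject, then tests each group's slopes against zero with a one-sample
#' t-test (one-tailed `slope > 0` for coarticulation-type measures,
#' two-tailed for duration-type measures).
#'
#' @param data Summary tibble restricted to the blocks of interest
#'   (typically training blocks 1-6).
#' @param dv Dependent variable column name.
#' @param over Column with the regressor (default `"block"`).
#' @param subject,group Identifier columns.
#' @param alternative `"greater"` (one-tailed, default) or `"two.sided"`.
#' @return A `coart_slopes` object with per-subject slopes and per-group
#'   tests; [tidy()] returns the group-level table.
#' @export
slope_analysis <- function(data, dv, over = "block", subject = "subject_id",
                           group = "group",
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- tibble::tibble(
    subject = as.character(data[[subject]]),
    grp = as.character(data[[group]]),
    x = as.numeric(data[[over]]),
    y = data[[dv]]
  )
  d <- d[stats::complete.cases(d), ]
  slopes <- d |>
    dplyr::group_by(.data$subject, .data$grp) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      slope = {
        if (dplyr::n() < 3) NA_real_
        else unname(stats::coef(stats::lm(y ~ x,
                                          data = dplyr::pick(dplyr::everything())))[2])
      },
      .groups = "drop"
    )
  if (anyNA(slopes$slope)) {
    stop("some subjects have fewer than 3 points for the slope fit",
         call. = FALSE)
  }
  tests <- slopes |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_slope = mean(.data$slope),
      se_slope = stats::sd(.data$slope) / sqrt(dplyr::n()),
      statistic = if (stats::sd(.data$slope) == 0) 0 else
        unname(stats::t.test(.data$slope, mu = 0,
                             alternative = alternative)$statistic),
      df = dplyr::n() - 1L,
      p_value = if (stats::sd(.data$slope) == 0) 1 else
        stats::t.test(.data$slope, mu = 0,
                      alternative = alternative)$p.value,
      .groups = "drop"
    ) |>
    dplyr::rename(group = "grp")
  structure(list(slopes = dplyr::rename(slopes, group = "grp"),
                 tests = tests, dv = dv, alternative = alternative),
            class = "coart_slopes")
}

#' @export
print.coart_slopes <- function(x, ...) {
  cat("Per-subject slopes of `", x$dv, "` (t-test vs 0, ",
      x$alternative, ")\n", sep = "")
  print(as.data.frame(x$tests), digits = 4)
  invisible(x)
}

#' @rdname slope_analysis
#' @param x A `coart_slopes` object.
#' @param ... Unused.
#' @export
tidy.coart_slopes <- function(x, ...) x$tests

#' Non-parametric battery for spatial error
#'
#' The within-subject route runs a Friedman test of `dv` over the levels of
#' `within` (matched by subject), followed by pairwise Wilcoxon signed-rank
#' tests (Bonferroni corrected). The between-subject route runs a
#' Kruskal-Wallis test over groups, followed by pairwise Mann-Whitney U
#' tests (Bonferroni corrected).
#'
#' @param data Summary tibble.
#' @param dv Dependent variable column name (default `"spatial_error"`).
#' @param design `"within"` (Friedman + Wilcoxon) or `"between"`
#'   (Kruskal-Wallis + Mann-Whitney).
#' @param within,between,subject Design columns.
#' @param posthoc Run the pairwise follow-ups (default `TRUE`).
#' @return List with `omnibus` (tidy one-row tibble) and `pairwise`
#'   (tibble of corrected comparisons), class `coart_nonparam`.
#' @export
nonparametric_battery <- function(data, dv = "spatial_error",
                                  design = c("within", "between"),
                                  within = "session", between = "group",
                                  subject = "subject_id", posthoc = TRUE) {
  design <- match.arg(design)
  if (design == "within") {
    d <- tibble::tibble(subject = as.character(data[[subject]]),
                        w = factor(data[[within]]),
                        y = data[[dv]])
    d <- d |>
      dplyr::group_by(.data$subject, .data$w) |>
      dplyr::summarise(y = mean(.data$y), .groups = "drop")
    wide <- tidyr::pivot_wider(d, names_from = "w", values_from = "y")
    lev <- levels(d$w)
    wide <- wide[stats::complete.cases(wide[, lev]), ]
    if (nrow(wide) < 2) stop("need >= 2 matched subjects", call. = FALSE)
    m <- as.matrix(wide[, lev])
    fr <- stats::friedman.test(m)
    stat <- unname(fr$statistic); pv <- fr$p.value
    if (is.nan(stat)) {      # fully tied data: no evidence of any effect
      stat <- 0; pv <- 1
    }
    omnibus <- tibble::tibble(
      test = "friedman", statistic = stat,
      df = unname(fr$parameter), p_value = pv
    )
    pairwise <- NULL
    if (posthoc && length(lev) >= 2) {
      cmb <- utils::combn(lev, 2)
      k <- ncol(cmb)
      pairwise <- purrr::map_dfr(seq_len(k), function(i) {
        a <- m[, cmb[1, i]]; b <- m[, cmb[2, i]]
        wt <- suppressWarnings(
          stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
        tibble::tibble(test = "wilcoxon-signed-rank",
                       level_1 = cmb[1, i], level_2 = cmb[2, i],
                       statistic = unname(wt$statistic),
                       p_raw = wt$p.value,
                       p_adjusted = min(1, wt$p.value * k))
      })
    }
  } else {
    d <- tibble::tibble(grp = factor(data[[between]]), y = data[[dv]],
                        subject = as.character(data[[subject]]))
    d <- d |>
      dplyr::group_by(.data$subject, .data$grp) |>
      dplyr::summarise(y = mean(.data$y), .groups = "drop")
    kw <- stats::kruskal.test(d$y, d$grp)
    stat <- unname(kw$statistic); pv <- kw$p.value
    if (is.nan(stat)) {      # fully tied data: no evidence of any effect
      stat <- 0; pv <- 1
    }
    omnibus <- tibble::tibble(
      test = "kruskal-wallis", statistic = stat,
      df = unname(kw$parameter), p_value = pv
    )
    pairwise <- NULL
    lev <- levels(droplevels(d$grp))
    if (posthoc && length(lev) >= 2) {
      cmb <- utils::combn(lev, 2)
      k <- ncol(cmb)
      pairwise <- purrr::map_dfr(seq_len(k), function(i) {
        a <- d$y[d$grp == cmb[1, i]]; b <- d$y[d$grp == cmb[2, i]]
        wt <- suppressWarnings(
          stats::wilcox.test(a, b, exact = FALSE))
        tibble::tibble(test = "mann-whitney",
                       level_1 = cmb[1, i], level_2 = cmb[2, i],
                       statistic = unname(wt$statistic),
                       p_raw = wt$p.value,
                       p_adjusted = min(1, wt$p.value * k))
      })
    }
  }
  structure(list(omnibus = omnibus, pairwise = pairwise, dv = dv,
                 design = design),
            class = "coart_nonparam")
}

#' @export
print.coart_nonparam <- function(x, ...) {
  cat("Non-parametric battery on `", x$dv, "` (", x$design, ")\n", sep = "")
  print(as.data.frame(x$omnibus), digits = 4)
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni):\n")
    print(as.data.frame(x$pairwise), digits = 4)
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Pairwise t-tests (paired or independent) between the levels of `by`,
#' with family-wise Bonferroni correction (raw p times the number of
#' comparisons, capped at 1).
#'
#' @param data Summary tibble.
#' @param dv Dependent variable column.
#' @param by Column whose levels are compared.
#' @param subject Subject column (used to pair observations when
#'   `paired = TRUE`, and to average replicates first).
#' @param paired Paired comparisons (within-subject levels) or independent.
#' @param levels Optional subset/order of levels to compare.
#' @return Tibble with one row per comparison: levels, mean difference,
#'   t statistic, df, raw and corrected p.
#' @export
posthoc_pairwise <- function(data, dv, by, subject = "subject_id",
                             paired = TRUE, levels = NULL) {
  d <- tibble::tibble(subject = as.character(data[[subject]]),
                      lv = as.character(data[[by]]),
                      y = data[[dv]])
  d <- d[stats::complete.cases(d), ] |>
    dplyr::group_by(.data$subject, .data$lv) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  if (is.null(levels)) levels <- unique(d$lv)
  cmb <- utils::combn(levels, 2)
  k <- ncol(cmb)
  purrr::map_dfr(seq_len(k), function(i) {
    la <- cmb[1, i]; lb <- cmb[2, i]
    if (paired) {
      wide <- tidyr::pivot_wider(
        d[d$lv %in% c(la, lb), ], names_from = "lv", values_from = "y")
      wide <- wide[stats::complete.cases(wide), ]
      tt <- stats::t.test(wide[[la]], wide[[lb]], paired = TRUE)
    } else {
      tt <- stats::t.test(d$y[d$lv == la], d$y[d$lv == lb])
    }
    tibble::tibble(
      level_1 = la, level_2 = lb,
      mean_diff = unname(if (paired) tt$estimate else
        tt$estimate[1] - tt$estimate[2]),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * k)
    )
  })
}

#' Transfer-condition battery
#'
#' Runs the day-2 battery over the trained (24 h), mirror and scaled test
#' sessions: mixed-design ANOVAs (group x transfer type) on normalized
#' duration, normalized coarticulation score, path offset and peak count,
#' plus the within-subject Friedman route for spatial error.
#'
#' @param summary_tbl Output of [summarize_measures()] containing sessions
#'   `day2`, `mirror` and `scaled`.
#' @param sessions The three transfer-phase session labels.
#' @return Named list: `duration`, `coart`, `path_offset`, `n_peaks`
#'   (each a `coart_anova`) and `spatial_error` (a `coart_nonparam`).
#' @export
transfer_analysis <- function(summary_tbl,
                              sessions = c("day2", "mirror", "scaled")) {
  d <- dplyr::filter(summary_tbl, .data$session %in% sessions)
  missing <- setdiff(sessions, unique(d$session))
  if (length(missing)) {
    stop("missing transfer session(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d$session <- factor(d$session, levels = sessions)
  list(
    duration = mixed_anova(d, "duration_norm"),
    coart = mixed_anova(d, "coart_norm"),
    path_offset = mixed_anova(d, "path_offset"),
    n_peaks = mixed_anova(d, "n_peaks"),
    spatial_error = nonparametric_battery(d, "spatial_error",
                                          design = "within")
  )
}

#' Type-I error of the interaction test on null data
#'
#' Simulates `n_rep` null datasets (independent standard-normal responses,
#' no group or session effects) with the given design shape, runs
#' [mixed_anova()] on each, and reports the fraction of interaction
#' p-values below `alpha`.
#'
#' @param n_rep Number of simulated null datasets.
#' @param n_per_group Subjects per group.
#' @param n_groups Number of groups.
#' @param n_within Number of within-subject levels.
#' @param alpha Nominal level (default 0.05).
#' @param seed RNG seed.
#' @return List with `rate`, `n_rep`, and the vector of interaction
#'   p-values.
#' @export
interaction_type1_rate <- function(n_rep = 500, n_per_group = 15,
                                   n_groups = 4, n_within = 3,
                                   alpha = 0.05, seed = 1) {
  set.seed(seed)
  pvals <- vapply(seq_len(n_rep), function(r) {
    d <- tidyr::expand_grid(
      subject_id = sprintf("s%03d", seq_len(n_per_group * n_groups)),
      session = paste0("w", seq_len(n_within))
    )
    d$group <- paste0("g", (match(d$subject_id, unique(d$subject_id)) - 1L) %%
                        n_groups + 1L)
    d$y <- stats::rnorm(nrow(d))
    fit <- mixed_anova(d, "y")
    fit$table$p_reported[fit$table$effect == "interaction"]
  }, numeric(1))
  list(rate = mean(pvals < alpha), n_rep = n_rep, p_values = pvals)
}
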