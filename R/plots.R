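# ggplot2 displays for the main result types.

#' Plot a trajectory over the target layout
#'
#' @param positions Tibble with `x`, `y` (cm), e.g. trial samples or a
#'   smoothed path.
#' @param layout A [target_layout()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(positions, layout) {
  ctr <- as.data.frame(target_centers(layout))
  ctr$label <- rownames(ctr)
  r <- target_radius_cm(layout)
  theta <- seq(0, 2 * pi, length.out = 60)
  discs <- purrr::map_dfr(seq_len(nrow(ctr)), function(i) {
    tibble::tibble(label = ctr$label[i],
                   x = ctr$x[i] + r * cos(theta),
                   y = ctr$y[i] + r * sin(theta))
  })
  ggplot2::ggplot(positions, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(data = discs,
                          ggplot2::aes(group = .data$label),
                          fill = "grey80", colour = "grey40") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_text(data = ctr, ggplot2::aes(label = .data$label),
                       nudge_y = 0.5, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-coartkin
#' @method autoplot velocity_profile
#' @export
autoplot.velocity_profile <- function(object, window = NULL, peaks = NULL,
                                      ...) {
  p <- ggplot2::ggplot(tibble::tibble(t = object$t, v = object$v),
                       ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "tangential velocity (cm/s)") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::geom_vline(xintercept = c(window$t_on, window$t_off),
                                 linetype = "dashed", colour = "grey40")
  }
  if (!is.null(peaks)) {
    pk <- peaks$peaks; tr <- peaks$troughs
    p <- p +
      ggplot2::geom_point(data = tibble::tibble(t = pk$t, v = pk$height),
                          colour = "firebrick", shape = 1, size = 2.5) +
      ggplot2::geom_point(data = tibble::tibble(t = tr$t, v = tr$height),
                          colour = "darkorange", shape = 0, size = 2.5)
  }
  p
}

#' Autoplot methods for coartkin result objects
#'
#' `autoplot.velocity_profile()` draws the tangential-velocity trace with
#' optional movement window and peak/trough markers;
#' `autoplot.simulation_curve()` shows the predicted coarticulation score
#' and curvature (path offset) as functions of submovement overlap.
#'
#' @param object The object to plot.
#' @param window Optional `movement_window` to mark on a velocity profile.
#' @param peaks Optional `peak_structure` to mark on a velocity profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-coartkin
#' @method autoplot simulation_curve
#' @export
autoplot.simulation_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("overlap", "score", "curvature_cm")],
    cols = c("score", "curvature_cm"),
    names_to = "measure", values_to = "value"
  )
  long$measure <- factor(long$measure, levels = c("score", "curvature_cm"),
                         labels = c("coarticulation score",
                                    "path offset (cm)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$overlap, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "submovement overlap (fraction of stroke duration)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Group learning curves
#'
#' Mean (across subjects) of a summary measure per block within each
#' session, with standard-error bars, one colour per group.
#'
#' @param summary_tbl Output of [summarize_measures()].
#' @param dv Column to display (default `"coart_score"`).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(summary_tbl, dv = "coart_score") {
  d <- summary_tbl |>
    dplyr::group_by(.data$group, .data$session, .data$block) |>
    dplyr::summarise(
      m = mean(.data[[dv]], na.rm = TRUE),
      se = stats::sd(.data[[dv]], na.rm = TRUE) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ord <- c("pre", "train", "post", "day2", "mirror", "scaled")
  d$session <- factor(d$session, levels = intersect(ord, unique(d$session)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$block, y = .data$m,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$se,
                                          ymax = .data$m + .data$se),
                             size = 0.25) +
    ggplot2::facet_grid(~session, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "block", y = dv, colour = "group") +
    ggplot2::theme_minimal()
}
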