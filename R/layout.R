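#' Define a four-target layout
#'
#' A layout is the task geometry: four labelled circular targets that must be
#' visited in alphabetical order and back to the start (A -> B -> C -> D -> A).
#' Centers are in cm (x rightward, y away from the body), target diameter in mm.
#'
#' @param targets Data frame with columns `label`, `x`, `y` (centers in cm).
#'   Must contain exactly the labels A, B, C, D.
#' @param diameter_mm Target diameter in mm (all targets share one diameter).
#' @param sequence Visiting order; the closing return to the first target is
#'   implicit.
#' @return A `target_layout` object: a list with elements `targets` (tibble),
#'   `diameter_mm` and `sequence`.
#' @examples
#' lay <- default_layout()
#' lay
#' @export
target_layout <- function(targets, diameter_mm = 5.4,
                          sequence = c("A", "B", "C", "D")) {
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("label", "x", "y") %in% names(targets)))
  if (nrow(targets) != 4L || anyDuplicated(targets$label) > 0L ||
      !setequal(targets$label, c("A", "B", "C", "D"))) {
    stop("a layout needs exactly four targets labelled A, B, C, D", call. = FALSE)
  }
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L || diameter_mm <= 0) {
    stop("`diameter_mm` must be a single positive number", call. = FALSE)
  }
  d <- as.matrix(stats::dist(targets[, c("x", "y")]))
  if (any(d[upper.tri(d)] < 1e-12)) {
    stop("target centers must be distinct", call. = FALSE)
  }
  if (!setequal(sequence, targets$label)) {
    stop("`sequence` must be a permutation of the target labels", call. = FALSE)
  }
  targets <- targets[match(c("A", "B", "C", "D"), targets$label),
                     c("label", "x", "y")]
  structure(
    list(targets = targets, diameter_mm = diameter_mm, sequence = sequence),
    class = "target_layout"
  )
}

#' Default target layout
#'
#' The packaged default geometry: A = (0, 0), B = (5.5, 3), C = (12, 0),
#' D = (6.5, -5.5) cm, diameter 5.4 mm. The quadrilateral forces a direction
#' change at B (shallow, ~53 degrees of heading change) and at D (sharp,
#' ~80 degrees), and a movement reversal at C. The two corners are
#' deliberately unequal: with a shallow turn at B the first submovement pair
#' blends into a single velocity peak at high overlap (the three-peak
#' profiles characteristic of strong A-B-C coarticulation), whereas the
#' sharp turn at D keeps its two peaks distinct, so the simulated peak count
#' steps 4 -> 3 at a single overlap value. An exactly symmetric layout would
#' merge both pairs simultaneously (4 -> 2) or, with two sharp corners,
#' never merge at all within the simulated overlap range.
#'
#' @return A [target_layout()].
#' @export
default_layout <- function() {
  target_layout(
    tibble::tibble(
      label = c("A", "B", "C", "D"),
      x = c(0, 5.5, 12, 6.5),
      y = c(0, 3, 0, -5.5)
    ),
    diameter_mm = 5.4
  )
}

#' @export
print.target_layout <- function(x, ...) {
  cat("<target_layout> ", paste(x$sequence, collapse = " -> "),
      " -> ", x$sequence[1], "; diameter ", x$diameter_mm, " mm\n", sep = "")
  print(x$targets)
  invisible(x)
}

#' Target centers in visiting order
#'
#' @param layout A [target_layout()].
#' @param close If `TRUE`, append the first target again so the matrix traces
#'   the closed path A -> B -> C -> D -> A.
#' @return Numeric matrix with columns `x`, `y`, row names = labels.
#' @export
target_centers <- function(layout, close = FALSE) {
  seq_lab <- layout$sequence
  if (close) seq_lab <- c(seq_lab, seq_lab[1])
  tg <- layout$targets[match(seq_lab, layout$targets$label), ]
  m <- as.matrix(tg[, c("x", "y")])
  rownames(m) <- tg$label
  m
}

#' Target radius in cm
#' @param layout A [target_layout()].
#' @return Radius in cm (diameter is stored in mm).
#' @export
target_radius_cm <- function(layout) layout$diameter_mm / 2 / 10

#' Mirror-reverse a layout
#'
#' Reflects the x coordinates about the vertical midline of the layout (the
#' line halfway between the leftmost and rightmost target centers). y
#' coordinates, diameter and visiting order (by label) are unchanged. This is
#' the mirror transfer condition: same dots, left-right reversed arrangement,
#' hence a mirror-reversed movement order in space.
#'
#' @param layout A [target_layout()].
#' @return The mirrored `target_layout`.
#' @export
mirror_layout <- function(layout) {
  mid <- (min(layout$targets$x) + max(layout$targets$x)) / 2
  tg <- layout$targets
  tg$x <- 2 * mid - tg$x
  target_layout(tg, layout$diameter_mm, layout$sequence)
}

#' Scale a layout about its centroid
#'
#' Shrinks (or keeps) inter-target distances by `factor` about the centroid of
#' the four centers; target diameter is left unchanged, as in the scaled
#' transfer condition (distances scaled down by 30%, original target sizes
#' maintained corresponds to `factor = 0.7`).
#'
#' @param layout A [target_layout()].
#' @param factor Scale factor in (0, 1].
#' @return The scaled `target_layout`.
#' @export
scale_layout <- function(layout, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("`factor` must be a single positive number", call. = FALSE)
  }
  tg <- layout$targets
  cx <- mean(tg$x); cy <- mean(tg$y)
  tg$x <- cx + factor * (tg$x - cx)
  tg$y <- cy + factor * (tg$y - cy)
  target_layout(tg, layout$diameter_mm, layout$sequence)
}

#' Read / write a layout as YAML
#'
#' The on-disk format has keys `layout.targets` (list of label/x/y), and
#' `layout.diameter_mm`, `layout.sequence`.
#'
#' @param path File path.
#' @return `read_layout()` returns a [target_layout()]; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layout)) stop("YAML file has no `layout` key", call. = FALSE)
  tg <- dplyr::bind_rows(lapply(cfg$layout$targets, tibble::as_tibble))
  target_layout(tg,
                diameter_mm = cfg$layout$diameter_mm %||% 5.4,
                sequence = unlist(cfg$layout$sequence %||% c("A", "B", "C", "D")))
}

#' @rdname read_layout
#' @param layout A [target_layout()] to serialize.
#' @export
write_layout <- function(layout, path) {
  cfg <- list(layout = list(
    targets = lapply(seq_len(4), function(i) {
      as.list(layout$targets[i, c("label", "x", "y")])
    }),
    diameter_mm = layout$diameter_mm,
    sequence = as.list(layout$sequence)
  ))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
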