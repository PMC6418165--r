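#' Build a trial set
#'
#' A trial set couples a table of stylus trials with the layout they were
#' recorded on and the nominal sampling rate. Trials are held in nested form:
#' one row per trial with identity columns and a `samples` list-column of
#' tibbles (`t` in s, `x`/`y` in cm).
#'
#' @param trials Nested tibble with columns `subject_id`, `group`, `session`,
#'   `block`, `trial`, `samples`, or a flat tibble with columns
#'   `subject_id, group, session, block, trial, t, x, y` (it is nested
#'   automatically).
#' @param layout A [target_layout()].
#' @param sample_rate_hz Nominal sampling rate (Hz).
#' @param provenance Free-text metadata string.
#' @return A `trial_set` object.
#' @export
trial_set <- function(trials, layout = default_layout(), sample_rate_hz = 160,
                      provenance = "") {
  trials <- tibble::as_tibble(trials)
  if (!"samples" %in% names(trials)) {
    stopifnot(all(c("t", "x", "y") %in% names(trials)))
    trials <- tidyr::nest(trials, samples = c("t", "x", "y"))
  }
  need <- c("subject_id", "group", "session", "block", "trial", "samples")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be positive", call. = FALSE)
  }
  trials <- trials[, need]
  validate_trials(trials)
  structure(
    list(trials = trials, layout = layout,
         sample_rate_hz = sample_rate_hz, provenance = provenance),
    class = "trial_set"
  )
}

trial_id_label <- function(row) {
  paste0(row$subject_id, "/", row$session, "/b", row$block, "/t", row$trial)
}

validate_trials <- function(trials) {
  for (i in seq_len(nrow(trials))) {
    s <- trials$samples[[i]]
    lab <- trial_id_label(trials[i, ])
    if (nrow(s) < 2L) {
      stop("trial ", lab, " has fewer than 2 samples", call. = FALSE)
    }
    if (any(diff(s$t) <= 0)) {
      stop("trial ", lab, " has non-increasing timestamps", call. = FALSE)
    }
    if (anyNA(s)) stop("trial ", lab, " contains missing samples", call. = FALSE)
  }
  invisible(trials)
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set> ", nrow(x$trials), " trials, ",
      dplyr::n_distinct(x$trials$subject_id), " subjects, ",
      x$sample_rate_hz, " Hz\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  print(x$layout)
  invisible(x)
}

#' @method as_tibble trial_set
#' @export
as_tibble.trial_set <- function(x, ...) {
  tidyr::unnest(x$trials, "samples")
}

trial_csv_cols <- c("subject_id", "group", "session", "block", "trial",
                    "t", "x", "y")

meta_path_for <- function(path) {
  sub("\\.csv$", ".meta.json", path)
}

#' Read stylus trials from CSV
#'
#' Reads the trial CSV dialect: columns exactly
#' `subject_id,group,session,block,trial,t,x,y` (t in s, x/y in cm, one row
#' per sample, '.' decimal, UTF-8, header required). A JSON sidecar
#' `<name>.meta.json`, if present, supplies the layout, sampling rate and
#' provenance; otherwise the package default layout and 160 Hz are assumed
#' with a message.
#'
#' @param path Path to the trial CSV.
#' @return A [trial_set()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  missing_cols <- setdiff(trial_csv_cols, trimws(header))
  if (length(missing_cols)) {
    stop("trial file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      session = readr::col_character(),
      block = readr::col_integer(),
      trial = readr::col_integer(),
      t = readr::col_double(),
      x = readr::col_double(),
      y = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(trial_csv_cols, names(raw))
  if (length(missing_cols)) {
    stop("trial file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop("malformed rows in ", path, ": ",
         paste0("line ", probs$row + 1L, " (", probs$expected, ")",
                collapse = "; "),
         call. = FALSE)
  }
  mp <- meta_path_for(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    layout <- target_layout(
      tibble::tibble(label = meta$layout$labels,
                     x = meta$layout$centers_cm[, 1],
                     y = meta$layout$centers_cm[, 2]),
      diameter_mm = meta$layout$diameter_mm,
      sequence = meta$layout$sequence
    )
    rate <- meta$sample_rate_hz
    prov <- meta$provenance %||% ""
  } else {
    message("no sidecar ", basename(mp), "; assuming default layout and 160 Hz")
    layout <- default_layout(); rate <- 160; prov <- ""
  }
  if (nrow(raw) == 0L) {
    trials <- tibble::tibble(
      subject_id = character(), group = character(), session = character(),
      block = integer(), trial = integer(), samples = list()
    )
    return(structure(list(trials = trials, layout = layout,
                          sample_rate_hz = rate, provenance = prov),
                     class = "trial_set"))
  }
  trial_set(raw, layout = layout, sample_rate_hz = rate, provenance = prov)
}

#' Write stylus trials to CSV
#'
#' Inverse of [read_trials()]: writes the flat sample table plus the
#' `<name>.meta.json` sidecar (layout, sampling rate, provenance). Sample
#' values round-trip losslessly to within 1e-15 relative error.
#'
#' @param tset A [trial_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(tset, path) {
  stopifnot(inherits(tset, "trial_set"))
  flat <- if (nrow(tset$trials)) {
    tidyr::unnest(tset$trials, "samples")[, trial_csv_cols]
  } else {
    tibble::new_tibble(stats::setNames(c(
      replicate(5, character(0), simplify = FALSE),
      replicate(3, numeric(0), simplify = FALSE)
    ), trial_csv_cols), nrow = 0L)
  }
  readr::write_csv(flat, path, progress = FALSE)
  meta <- list(
    layout = list(
      labels = tset$layout$targets$label,
      centers_cm = unname(as.matrix(tset$layout$targets[, c("x", "y")])),
      diameter_mm = tset$layout$diameter_mm,
      sequence = tset$layout$sequence
    ),
    sample_rate_hz = tset$sample_rate_hz,
    provenance = tset$provenance
  )
  jsonlite::write_json(meta, meta_path_for(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
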