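#' Read a fixation table from delimited text
#'
#' Reads a CSV/TSV file of pre-detected fixations into the canonical fixation
#' tibble used throughout the package. Column names in the file are resolved
#' through `mapping`, so vendor exports with arbitrary headers can be ingested
#' without editing the file.
#'
#' Required logical columns are `participant`, `trial`, `start` and
#' `duration`, plus either `label` or both `x` and `y`. Any unmapped columns
#' are preserved untouched as metadata. Rows are grouped by (participant,
#' trial) and time-sorted within each trial.
#'
#' @param path Path to a delimited text file with a header row.
#' @param mapping Named list or character vector translating logical column
#'   names to file column names, e.g. `list(start = "Event Start Trial Time [ms]")`.
#'   Logical names: `participant`, `group`, `trial`, `start`, `duration`,
#'   `x`, `y`, `label`. Unspecified entries default to the canonical names
#'   (`participant`, `group`, `trial`, `start_ms`, `duration_ms`, `x`, `y`,
#'   `label`).
#' @param delim Field delimiter; `NULL` (default) guesses from the file
#'   extension (`.tsv`/`.tab` gives tab, otherwise comma).
#'
#' @return A tibble with columns `participant`, `group`, `trial`, `start_ms`,
#'   `duration_ms`, `x`, `y`, `label` (missing optional columns filled with
#'   `NA`), sorted by participant, trial, start time, plus any metadata
#'   columns from the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subj,run,t0,dur,aoi",
#'              "p1,1,0,120,A", "p1,1,120,90,A", "p1,1,210,200,B"), f)
#' read_fixations(f, mapping = list(participant = "subj", trial = "run",
#'                                  start = "t0", duration = "dur", label = "aoi"))
read_fixations <- function(path, mapping = list(), delim = NULL) {
  canon <- c(participant = "participant", group = "group", trial = "trial",
             start = "start_ms", duration = "duration_ms",
             x = "x", y = "y", label = "label")
  mapping <- utils::modifyList(as.list(canon), as.list(mapping))

  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)

  required <- c("participant", "trial", "start", "duration")
  for (fld in required) {
    if (!mapping[[fld]] %in% names(raw)) {
      stop("read_fixations(): required column '", mapping[[fld]],
           "' (", fld, ") not found in ", path, call. = FALSE)
    }
  }
  has_label <- mapping[["label"]] %in% names(raw)
  has_xy <- all(c(mapping[["x"]], mapping[["y"]]) %in% names(raw))
  if (!has_label && !has_xy) {
    stop("read_fixations(): need either a '", mapping[["label"]],
         "' column or both '", mapping[["x"]], "' and '", mapping[["y"]],
         "' columns", call. = FALSE)
  }

  pick <- function(fld, default = NA) {
    col <- mapping[[fld]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  num <- function(v, fld) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0) {
      stop("read_fixations(): non-numeric value in '", mapping[[fld]],
           "' at data row ", bad[1], call. = FALSE)
    }
    out
  }

  fx <- tibble::tibble(
    participant = as.character(pick("participant")),
    group       = as.character(pick("group", NA_character_)),
    trial       = as.integer(num(pick("trial"), "trial")),
    start_ms    = num(pick("start"), "start"),
    duration_ms = num(pick("duration"), "duration"),
    x           = if (has_xy) num(pick("x"), "x") else NA_real_,
    y           = if (has_xy) num(pick("y"), "y") else NA_real_,
    label       = if (has_label) as.character(pick("label")) else NA_character_
  )
  meta_cols <- setdiff(names(raw), unlist(mapping))
  if (length(meta_cols) > 0) fx <- dplyr::bind_cols(fx, raw[meta_cols])

  dplyr::arrange(fx, .data$participant, .data$trial, .data$start_ms)
}

#' Write the canonical fixation table
#'
#' @param fixations Fixation tibble as returned by [read_fixations()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  readr::write_csv(fixations, path, progress = FALSE)
  invisible(path)
}

#' Detect fixations from raw gaze samples (I-VT)
#'
#' Velocity-threshold identification: point-to-point velocities between
#' consecutive valid samples are compared against `velocity_threshold`;
#' maximal runs of samples connected by sub-threshold velocities form
#' candidate fixations, and candidates shorter than `min_duration` are
#' discarded. Invalid samples always split candidates (a blink never bridges
#' two fixations). Defaults follow the common vendor settings of a 50 ms
#' minimum duration and a 40 deg/s peak velocity.
#'
#' Velocities are computed in the units of the input per second: if `x`/`y`
#' are pixels, supply `px_per_degree` to interpret `velocity_threshold` in
#' degrees per second; otherwise the threshold is taken in input units.
#' An optional centered moving-average smoothing of the velocity trace is
#' available via `smooth_window` (number of velocity points; off by default).
#'
#' @param samples Tibble/data.frame with columns `t` (ms, strictly
#'   increasing), `x`, `y`, and optionally `valid` (logical, default all
#'   `TRUE`).
#' @param velocity_threshold Saccade velocity threshold, per second
#'   (default 40; degrees if `px_per_degree` is given, else input units).
#' @param min_duration Minimum fixation duration in ms (default 50).
#' @param px_per_degree Optional pixels-per-degree conversion; when given,
#'   velocities are divided by it before comparison so the threshold is in
#'   deg/s.
#' @param smooth_window Optional odd integer width of a centered
#'   moving-average applied to the velocity trace; `NULL` (default) disables
#'   smoothing.
#'
#' @return Tibble of fixations with columns `start_ms`, `duration_ms`, `x`,
#'   `y` (centroids), `n_samples`. Fewer than two valid samples yields an
#'   empty (zero-row) tibble.
#' @export
#' @examples
#' t <- seq(0, by = 1000 / 60, length.out = 13)
#' detect_fixations(data.frame(t = t, x = 100, y = 100))
detect_fixations <- function(samples, velocity_threshold = 40,
                             min_duration = 50, px_per_degree = NULL,
                             smooth_window = NULL) {
  stopifnot(velocity_threshold > 0, min_duration >= 0)
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  if (is.unsorted(samples$t, strictly = TRUE)) {
    stop("detect_fixations(): sample timestamps must be strictly increasing",
         call. = FALSE)
  }

  empty <- tibble::tibble(start_ms = numeric(), duration_ms = numeric(),
                          x = numeric(), y = numeric(), n_samples = integer())
  v <- samples[samples$valid & !is.na(samples$x) & !is.na(samples$y), ,
               drop = FALSE]
  if (nrow(v) < 2) return(empty)

  dt <- diff(v$t)                       # ms
  disp <- sqrt(diff(v$x)^2 + diff(v$y)^2)
  vel <- disp / (dt / 1000)             # units per s
  if (!is.null(px_per_degree)) vel <- vel / px_per_degree
  if (!is.null(smooth_window) && smooth_window > 1) {
    vel <- stats::filter(vel, rep(1 / smooth_window, smooth_window),
                         sides = 2)
    vel[is.na(vel)] <- Inf              # edges: do not invent sub-threshold links
  }

  # a link is fixational iff below threshold AND the two samples were adjacent
  # in the original recording (an invalid sample in between breaks the link)
  idx <- which(samples$valid & !is.na(samples$x) & !is.na(samples$y))
  adjacent <- diff(idx) == 1
  link <- (vel < velocity_threshold) & adjacent

  period <- stats::median(dt)
  runs <- rle(link)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    member <- seq(starts[i], ends[i] + 1)   # link j joins samples j, j+1
    dur <- v$t[member[length(member)]] - v$t[member[1]] + period
    if (dur < min_duration) next
    out[[length(out) + 1]] <- tibble::tibble(
      start_ms = v$t[member[1]],
      duration_ms = dur,
      x = mean(v$x[member]),
      y = mean(v$y[member]),
      n_samples = length(member)
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}
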