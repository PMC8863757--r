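#' Collapse consecutive same-AOI fixations into dwells
#'
#' A dwell is a maximal run of consecutive fixations on the same AOI. The
#' collapsed representation keeps one letter per dwell, so no letter in the
#' resulting string neighbors itself — the property the whole k-mer machinery
#' relies on. Dwell time aggregates the member fixation durations.
#'
#' @param fixations Labeled fixation tibble (see [label_fixations()]); must
#'   carry `participant`, `trial`, `label`, `duration_ms`, ordered in time
#'   within each trial. A `group` column is carried through if present.
#' @return Tibble of dwells with columns `participant`, `group`, `trial`,
#'   `position` (1-based within trial), `letter`, `dwell_ms` (sum of member
#'   fixation durations) and `n_fixations`.
#' @export
#' @examples
#' fx <- tibble::tibble(participant = "p1", group = "NOV BC", trial = 1L,
#'                      start_ms = c(0, 100, 250, 450, 500),
#'                      duration_ms = c(100, 150, 200, 50, 80),
#'                      label = c("A", "A", "B", "B", "A"))
#' collapse_dwells(fx)
collapse_dwells <- function(fixations) {
  cols <- c("participant", "group", "trial", "position", "letter",
            "dwell_ms", "n_fixations")
  if (nrow(fixations) == 0) {
    return(tibble::tibble(participant = character(), group = character(),
                          trial = integer(), position = integer(),
                          letter = character(), dwell_ms = numeric(),
                          n_fixations = integer()))
  }
  if (any(is.na(fixations$label))) {
    stop("collapse_dwells(): unlabeled fixations present; run label_fixations() first",
         call. = FALSE)
  }
  if (!"group" %in% names(fixations)) fixations$group <- NA_character_

  fixations |>
    dplyr::group_by(.data$participant, .data$group, .data$trial) |>
    dplyr::group_modify(function(df, key) {
      r <- rle(df$label)
      run_id <- rep(seq_along(r$lengths), r$lengths)
      tibble::tibble(
        position = seq_along(r$values),
        letter = r$values,
        dwell_ms = as.numeric(tapply(df$duration_ms, run_id, sum)),
        n_fixations = as.integer(r$lengths)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(cols))
}

#' One collapsed letter string per trial
#'
#' @param dwells Dwell tibble from [collapse_dwells()].
#' @return Tibble with columns `participant`, `group`, `trial`, `string`
#'   (the trial's collapsed AOI letter sequence), `n_dwells`.
#' @export
dwell_strings <- function(dwells) {
  if (nrow(dwells) == 0) {
    return(tibble::tibble(participant = character(), group = character(),
                          trial = integer(), string = character(),
                          n_dwells = integer()))
  }
  dwells |>
    dplyr::arrange(.data$participant, .data$trial, .data$position) |>
    dplyr::group_by(.data$participant, .data$group, .data$trial) |>
    dplyr::summarise(string = paste(.data$letter, collapse = ""),
                     n_dwells = dplyr::n(), .groups = "drop")
}

#' Traditional eye-tracking metrics per trial
#'
#' Computes, per (participant, trial): mean fixation duration, per-AOI dwell
#' time and dwell count, and ordered AOI transition counts. Dwell count per
#' AOI equals the k = 1 k-mer count of the collapsed string, and the
#' transition counts equal its k = 2 k-mer counts — the bridge between
#' traditional AOI metrics and the k-mer view.
#'
#' @param fixations Labeled fixation tibble.
#' @param include_whitespace Include whitespace fixations in the mean
#'   fixation duration (default `TRUE`).
#' @param whitespace_letter Letter treated as whitespace for the option
#'   above (default `"W"`).
#' @return List of three tibbles: `fixation` (participant, group, trial,
#'   mean_fixation_ms, n_fixations), `dwell` (participant, group, trial,
#'   letter, dwell_time_s, dwell_count) and `transition` (participant, group,
#'   trial, transition, count).
#' @export
trial_metrics <- function(fixations, include_whitespace = TRUE,
                          whitespace_letter = "W") {
  dw <- collapse_dwells(fixations)
  if (!"group" %in% names(fixations)) fixations$group <- NA_character_

  fx_use <- if (include_whitespace) fixations else
    fixations[fixations$label != whitespace_letter, , drop = FALSE]
  fix_tbl <- fx_use |>
    dplyr::group_by(.data$participant, .data$group, .data$trial) |>
    dplyr::summarise(mean_fixation_ms = mean(.data$duration_ms),
                     n_fixations = dplyr::n(), .groups = "drop")

  dwell_tbl <- dw |>
    dplyr::group_by(.data$participant, .data$group, .data$trial, .data$letter) |>
    dplyr::summarise(dwell_time_s = sum(.data$dwell_ms) / 1000,
                     dwell_count = dplyr::n(), .groups = "drop")

  strings <- dwell_strings(dw)
  trans_tbl <- purrr::pmap_dfr(strings, function(participant, group, trial,
                                                 string, n_dwells) {
    L <- nchar(string)
    if (L < 2) {
      return(tibble::tibble(participant = character(), group = character(),
                            trial = integer(), transition = character(),
                            count = integer()))
    }
    tt <- table(substring(string, 1:(L - 1), 2:L))
    tibble::tibble(participant = participant, group = group, trial = trial,
                   transition = names(tt), count = as.integer(tt))
  })

  list(fixation = fix_tbl, dwell = dwell_tbl, transition = trans_tbl)
}
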