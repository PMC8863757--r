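#' Per-trial pattern count series
#'
#' Expands a long k-mer table into dense per-participant, per-pattern series
#' over trials: a trial in which the pattern does not occur contributes an
#' explicit zero, so every series covers all of the participant's trials.
#'
#' @param kmers Long k-mer table from [kmer_table()].
#' @param patterns Character vector of patterns to track (the pattern length
#'   is read off each pattern). Defaults to all patterns present.
#' @return Tibble with columns `participant`, `group`, `pattern`, `trial`,
#'   `count`, sorted by trial within each series.
#' @export
build_series <- function(kmers, patterns = NULL) {
  if (is.null(patterns)) patterns <- unique(kmers$pattern)
  trials <- kmers |>
    dplyr::distinct(.data$participant, .data$group, .data$trial)
  if (nrow(trials) == 0) {
    stop("build_series(): no trials in input", call. = FALSE)
  }
  grid <- tidyr::crossing(trials, pattern = patterns)
  counts <- kmers |>
    dplyr::filter(.data$pattern %in% patterns) |>
    dplyr::select(dplyr::all_of(c("participant", "group", "trial", "pattern",
                                  "count")))
  grid |>
    dplyr::left_join(counts,
                     by = c("participant", "group", "trial", "pattern")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$participant, .data$pattern, .data$trial)
}

#' Per-participant linear learning trends
#'
#' Ordinary least squares of pattern count on the centered trial index
#' (`trial - mean(trial)`) for each (participant, pattern) series. Centering
#' makes the intercept the fitted value at the mean trial — identical, under
#' OLS, to the participant's average pattern count — so between-group
#' intercept comparisons measure average pattern occurrence while slopes
#' measure learning rate in counts per trial.
#'
#' @param series Dense series tibble from [build_series()].
#' @return Tibble with columns `participant`, `group`, `pattern`, `slope`
#'   (count per trial), `intercept` (centered), `sigma2` (residual variance,
#'   `SSR / (n - 2)`), `n_trials`.
#' @export
#' @examples
#' s <- tibble::tibble(participant = "p", group = "NOV BC", pattern = "BABA",
#'                     trial = 1:4, count = c(1, 2, 3, 4))
#' fit_trends(s)  # slope 1, intercept 2.5
fit_trends <- function(series) {
  series |>
    dplyr::group_by(.data$participant, .data$group, .data$pattern) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        stop("fit_trends(): series for participant '", key$participant,
             "', pattern '", key$pattern, "' has fewer than 2 trials",
             call. = FALSE)
      }
      fit <- stats::lm(count ~ I(trial - mean(trial)), data = df)
      cf <- stats::coef(fit)
      tibble::tibble(
        slope = unname(cf[2]),
        intercept = unname(cf[1]),
        sigma2 = if (nrow(df) > 2) sum(stats::resid(fit)^2) / (nrow(df) - 2)
                 else NA_real_,
        n_trials = nrow(df)
      )
    }) |>
    dplyr::ungroup()
}

#' Group learning curves (mean and SEM per trial)
#'
#' @param series Dense series tibble from [build_series()].
#' @return Tibble with columns `group`, `pattern`, `trial`, `mean`, `sem`
#'   (sample SD over participants divided by sqrt(n); `NA` when only one
#'   participant contributes) and `n`.
#' @export
group_curves <- function(series) {
  series |>
    dplyr::group_by(.data$group, .data$pattern, .data$trial) |>
    dplyr::summarise(
      mean = mean(.data$count),
      sem = if (dplyr::n() > 1) stats::sd(.data$count) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(),
      .groups = "drop")
}

#' Plot group learning curves
#'
#' Convenience ggplot of per-trial pattern means with SEM ribbons, one panel
#' per pattern, colored by group. Requires ggplot2.
#'
#' @param curves Output of [group_curves()].
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_learning_curves() requires the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$trial, y = .data$mean,
                               color = .data$group, group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - dplyr::coalesce(.data$sem, 0),
                   ymax = .data$mean + dplyr::coalesce(.data$sem, 0)),
      fatten = 1.5) +
    ggplot2::facet_wrap(~pattern, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = "Pattern count (mean ± SEM)") +
    ggplot2::theme_minimal()
}
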