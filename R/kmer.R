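#' Count overlapping k-mers of a string
#'
#' Counts every length-`k` window of `s` at stride 1 (standard k-mer
#' semantics). On a collapsed dwell string this makes k = 1 counts identical
#' to per-AOI dwell counts and k = 2 counts identical to ordered AOI
#' transition counts. Patterns absent from `s` are absent from the result
#' (implicitly zero).
#'
#' @param s Character scalar (a collapsed AOI letter string).
#' @param k Window length, integer >= 1.
#' @return Named integer vector of counts; total is `max(0, nchar(s) - k + 1)`.
#' @export
#' @examples
#' count_kmers("ABABAB", 2)  # AB: 3, BA: 2
count_kmers <- function(s, k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k)) {
    stop("count_kmers(): k must be a single integer >= 1", call. = FALSE)
  }
  L <- nchar(s)
  if (L < k) return(stats::setNames(integer(0), character(0)))
  windows <- substring(s, 1:(L - k + 1), k:L)
  tt <- table(windows)
  stats::setNames(as.integer(tt), names(tt))
}

#' Long-format k-mer count table over trials
#'
#' Applies [count_kmers()] to every trial string for each requested `k`.
#'
#' @param strings Trial-string tibble from [dwell_strings()] (columns
#'   `participant`, `group`, `trial`, `string`).
#' @param k Integer vector of pattern lengths (default `c(1, 2, 3, 4, 6)`).
#' @return Tibble with columns `participant`, `group`, `trial`, `k`,
#'   `pattern`, `count` — one row per pattern observed in a trial.
#' @export
kmer_table <- function(strings, k = c(1, 2, 3, 4, 6)) {
  stopifnot(all(k >= 1))
  purrr::map_dfr(sort(unique(as.integer(k))), function(kk) {
    purrr::pmap_dfr(strings[c("participant", "group", "trial", "string")],
                    function(participant, group, trial, string) {
      cnt <- count_kmers(string, kk)
      if (length(cnt) == 0) {
        return(tibble::tibble(participant = character(), group = character(),
                              trial = integer(), k = integer(),
                              pattern = character(), count = integer()))
      }
      tibble::tibble(participant = participant, group = group, trial = trial,
                     k = kk, pattern = names(cnt), count = unname(cnt))
    })
  })
}

#' Relative pattern frequencies
#'
#' For each `k`, a pattern's count is first averaged over each participant's
#' trials (a trial where the pattern does not occur contributes zero), those
#' per-participant means are averaged within the grouping unit, and the
#' result is normalized by the sum over all same-k patterns — so relative
#' frequencies of one `k` sum to 1 whenever any pattern was observed.
#'
#' @param kmers Long k-mer table from [kmer_table()].
#' @param by Grouping unit: `"group"` (default; pooled over the group's
#'   participants) or `"participant"`.
#' @return Tibble with the grouping column(s), `k`, `pattern`, `mean_count`
#'   (the averaged appearance frequency), `rel_freq`, and `sem` (standard
#'   error of the per-participant means; `NA` for `by = "participant"` or
#'   single-participant groups).
#' @export
relative_frequency <- function(kmers, by = c("group", "participant")) {
  by <- match.arg(by)
  if (nrow(kmers) == 0) {
    return(tibble::tibble(group = character(), k = integer(),
                          pattern = character(), mean_count = numeric(),
                          rel_freq = numeric(), sem = numeric()))
  }

  # per-participant mean count across that participant's trials,
  # with zeros for trials where the pattern is absent
  trials_per <- kmers |>
    dplyr::distinct(.data$participant, .data$group, .data$trial) |>
    dplyr::count(.data$participant, .data$group, name = "n_trials")
  per_part <- kmers |>
    dplyr::group_by(.data$participant, .data$group, .data$k, .data$pattern) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(trials_per, by = c("participant", "group")) |>
    dplyr::mutate(mean_count = .data$total / .data$n_trials)

  if (by == "participant") {
    out <- per_part |>
      dplyr::group_by(.data$participant, .data$group, .data$k) |>
      dplyr::mutate(rel_freq = .data$mean_count / sum(.data$mean_count),
                    sem = NA_real_) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c("participant", "group", "k", "pattern",
                                    "mean_count", "rel_freq", "sem")))
    return(dplyr::arrange(out, .data$participant, .data$k,
                          dplyr::desc(.data$rel_freq)))
  }

  # pool over the group's participants: absent pattern = 0 for that participant
  n_part <- per_part |>
    dplyr::distinct(.data$group, .data$participant) |>
    dplyr::count(.data$group, name = "n_participants")
  out <- per_part |>
    dplyr::left_join(n_part, by = "group") |>
    dplyr::group_by(.data$group, .data$k, .data$pattern) |>
    dplyr::summarise(
      n_participants = .data$n_participants[1],
      sem = if (.data$n_participants[1] > 1) {
        m <- c(.data$mean_count, rep(0, .data$n_participants[1] - dplyr::n()))
        stats::sd(m) / sqrt(length(m))
      } else NA_real_,
      mean_count = sum(.data$mean_count) / .data$n_participants[1],
      .groups = "drop_last") |>
    dplyr::mutate(rel_freq = .data$mean_count / sum(.data$mean_count),
                  sem = .data$sem / sum(.data$mean_count)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("group", "k", "pattern", "mean_count",
                                  "rel_freq", "sem")))
  dplyr::arrange(out, .data$group, .data$k, dplyr::desc(.data$rel_freq))
}

#' Relevant gaze patterns
#'
#' Selects patterns whose relative frequency strictly exceeds the threshold
#' (default the conventional "more than 1 percent" rule).
#'
#' @param rel_freq Either the tibble from [relative_frequency()] or a named
#'   numeric vector of relative frequencies.
#' @param threshold Strict lower cutoff in `[0, 1)`, default `0.01`.
#' @return Filtered tibble (same columns), or for a named vector input, the
#'   character vector of surviving pattern names.
#' @export
relevant_patterns <- function(rel_freq, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold < 1)
  if (is.numeric(rel_freq)) {
    return(names(rel_freq)[rel_freq > threshold])
  }
  rel_freq[rel_freq$rel_freq > threshold, , drop = FALSE]
}

#' Size of the possible pattern space
#'
#' Number of distinct length-`k` strings over `n_aoi` letters. With
#' `collapsed = TRUE` (the default, matching collapsed dwell strings) only
#' strings with no letter adjacent to itself are counted:
#' `n_aoi * (n_aoi - 1)^(k - 1)`. With `collapsed = FALSE` all `n_aoi^k`
#' strings count.
#'
#' @param n_aoi Number of AOI letters, >= 1.
#' @param k Pattern length, >= 1.
#' @param collapsed Restrict to no-adjacent-repeat strings (default `TRUE`).
#' @return Integer count (0 when `n_aoi = 1`, `collapsed = TRUE`, `k > 1`).
#' @export
#' @examples
#' count_possible_patterns(4, 4)          # 108
#' count_possible_patterns(4, 3, collapsed = FALSE)  # 64
count_possible_patterns <- function(n_aoi, k, collapsed = TRUE) {
  stopifnot(n_aoi >= 1, k >= 1)
  if (collapsed) n_aoi * (n_aoi - 1)^(k - 1) else n_aoi^k
}

#' Enumerate the possible pattern space
#'
#' Explicit generation companion to [count_possible_patterns()]; useful for
#' dense output tables and for cross-checking the closed form.
#'
#' @param alphabet Character vector of AOI letters.
#' @param k Pattern length.
#' @param collapsed Exclude strings with adjacent repeats (default `TRUE`).
#' @return Character vector of all possible patterns.
#' @export
enumerate_patterns <- function(alphabet, k, collapsed = TRUE) {
  stopifnot(length(alphabet) >= 1, k >= 1)
  pats <- alphabet
  for (i in seq_len(k - 1)) {
    pats <- as.vector(outer(pats, alphabet, paste0))
    if (collapsed) {
      last <- substring(pats, nchar(pats) - 1, nchar(pats) - 1)
      new <- substring(pats, nchar(pats), nchar(pats))
      pats <- pats[last != new]
    }
  }
  sort(pats)
}

#' Restrict a k-mer table to an AOI sub-alphabet
#'
#' Drops every pattern containing a letter outside `keep`; any `rel_freq`
#' column is renormalized over the survivors (within group/participant and
#' k). Supports result tables that report only task-relevant AOIs and omit
#' whitespace.
#'
#' @param kmers Long tibble with a `pattern` column ([kmer_table()] or
#'   [relative_frequency()] output).
#' @param keep Character vector of letters to keep; must be non-empty.
#' @return The filtered (and, if applicable, renormalized) tibble.
#' @export
restrict_alphabet <- function(kmers, keep) {
  if (length(keep) == 0) {
    stop("restrict_alphabet(): keep must contain at least one letter",
         call. = FALSE)
  }
  ok <- vapply(strsplit(kmers$pattern, ""),
               function(ch) all(ch %in% keep), logical(1))
  out <- kmers[ok, , drop = FALSE]
  if ("rel_freq" %in% names(out) && nrow(out) > 0) {
    grp_cols <- intersect(c("participant", "group", "k"), names(out))
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
      dplyr::mutate(rel_freq = .data$rel_freq / sum(.data$rel_freq)) |>
      dplyr::ungroup()
  }
  out
}
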