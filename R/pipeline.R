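#' Simulate a cohort and write it to disk
#'
#' Writes the canonical fixation CSV (`cohort.csv`) and a ground-truth JSON
#' (`truth.json`: kernels, learning rates, seed, expected k-mer frequencies
#' per group and trial) into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param spec A [synth_spec()]; default the standard two-novice-group plus
#'   experts design (30 participants x 8 trials).
#' @param seed Integer master seed (default 1).
#' @return Invisibly, a list of the paths written.
#' @export
run_simulate <- function(out_dir, spec = synth_spec(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec, seed = seed)
  cohort_path <- file.path(out_dir, "cohort.csv")
  truth_path <- file.path(out_dir, "truth.json")
  write_fixations(cohort$fixations, cohort_path)
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor", pretty = TRUE)
  message("run_simulate: wrote ",
          nrow(dplyr::distinct(cohort$fixations,
                               .data$participant, .data$trial)),
          " gaze sequences to ", cohort_path)
  invisible(list(cohort = cohort_path, truth = truth_path))
}

#' Run the full analysis pipeline on a fixation table
#'
#' End-to-end: (optional) AOI labeling, dwell collapsing, k-mer counting,
#' relative frequencies with the relevance filter, per-participant trends,
#' group learning curves, and the statistical battery. All stages are
#' deterministic, so identical input and configuration give identical
#' outputs.
#'
#' @param fixations Canonical fixation tibble, or a path to a fixation CSV
#'   readable by [read_fixations()].
#' @param out_dir Optional output directory; when given, writes
#'   `kmer_counts.csv`, `relative_frequency.csv`, `relevant_patterns.csv`,
#'   `trends.csv`, `curves.csv`, `stats.json`, `stats_paired.csv`,
#'   `stats_anova.csv` and `run_log.txt`.
#' @param scheme Optional [aoi_scheme()] for unlabeled fixations.
#' @param k Pattern lengths to count (default `c(1, 2, 3, 4, 6)`).
#' @param alphabet Optional restriction of result tables to these letters
#'   (e.g. `c("A", "B", "C")` to drop whitespace-containing patterns);
#'   `NULL` keeps everything.
#' @param threshold Relevance cutoff on relative frequency (strict `>`,
#'   default 0.01).
#' @param track_patterns Patterns whose trial trends and statistics are
#'   reported; `NULL` (default) tracks every relevant pattern of every
#'   group.
#' @param exclude_groups Groups excluded from inferential statistics
#'   (default `"EXP"`).
#' @param alpha Significance level (default 0.05).
#' @return List with elements `dwells`, `strings`, `metrics`, `kmers`,
#'   `rel_freq`, `relevant`, `series`, `trends`, `curves`, `stats`.
#' @export
run_analyze <- function(fixations, out_dir = NULL, scheme = NULL,
                        k = c(1, 2, 3, 4, 6), alphabet = NULL,
                        threshold = 0.01, track_patterns = NULL,
                        exclude_groups = "EXP", alpha = 0.05) {
  if (is.character(fixations)) fixations <- read_fixations(fixations)
  if (nrow(fixations) == 0) {
    stop("run_analyze(): empty cohort", call. = FALSE)
  }
  fixations <- label_fixations(fixations, scheme)

  dwells <- collapse_dwells(fixations)
  strings <- dwell_strings(dwells)
  metrics <- trial_metrics(fixations)
  kmers <- kmer_table(strings, k = k)
  if (!is.null(alphabet)) kmers <- restrict_alphabet(kmers, alphabet)
  rel <- relative_frequency(kmers, by = "group")
  relevant <- relevant_patterns(rel, threshold = threshold)

  if (is.null(track_patterns)) {
    track_patterns <- unique(relevant$pattern[relevant$k > 1])
  }
  series <- build_series(kmers, patterns = track_patterns)
  trends <- fit_trends(series)
  curves <- group_curves(series)
  stats_out <- pattern_stats(series, trends, exclude_groups = exclude_groups,
                             alpha = alpha)

  res <- list(dwells = dwells, strings = strings, metrics = metrics,
              kmers = kmers, rel_freq = rel, relevant = relevant,
              series = series, trends = trends, curves = curves,
              stats = stats_out)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(kmers, file.path(out_dir, "kmer_counts.csv"),
                     progress = FALSE)
    readr::write_csv(rel, file.path(out_dir, "relative_frequency.csv"),
                     progress = FALSE)
    readr::write_csv(relevant, file.path(out_dir, "relevant_patterns.csv"),
                     progress = FALSE)
    readr::write_csv(trends, file.path(out_dir, "trends.csv"),
                     progress = FALSE)
    readr::write_csv(curves, file.path(out_dir, "curves.csv"),
                     progress = FALSE)
    readr::write_csv(stats_out$paired, file.path(out_dir, "stats_paired.csv"),
                     progress = FALSE)
    readr::write_csv(stats_out$anova, file.path(out_dir, "stats_anova.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(schema_version = "1.0",
           config = list(k = k, alphabet = alphabet, threshold = threshold,
                         track_patterns = track_patterns,
                         exclude_groups = exclude_groups, alpha = alpha),
           paired = stats_out$paired, anova = stats_out$anova,
           levene = stats_out$levene),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, dataframe = "rows")
    writeLines(c(
      paste0("gazekmer ", as.character(utils::packageVersion("gazekmer"))),
      paste0("R ", R.version.string),
      paste0("k = {", paste(k, collapse = ","), "}, threshold = ", threshold,
             ", alpha = ", alpha),
      paste0("tracked patterns: ", paste(track_patterns, collapse = ", ")),
      paste0("participants: ",
             length(unique(fixations$participant)),
             ", trials: ", length(unique(fixations$trial)),
             ", fixations: ", nrow(fixations))),
      file.path(out_dir, "run_log.txt"))
  }
  res
}
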