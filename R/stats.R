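#' Levene's test of equal variances
#'
#' Classic (mean-centered) Levene: a one-way ANOVA of the absolute
#' deviations of each observation from its group mean. The median-centered
#' Brown-Forsythe variant is available via `center = "median"`.
#'
#' @param values Numeric vector of observations.
#' @param group Factor/character vector of group membership, same length.
#' @param center `"mean"` (classic, default) or `"median"` (Brown-Forsythe).
#' @return List of class `levene_result` with `W` (the F statistic of the
#'   deviation ANOVA), `df` (c(between, within)) and `p`.
#' @export
#' @examples
#' levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))  # W = 0
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- factor(group)
  if (nlevels(group) < 2) {
    stop("levene_test(): need at least 2 groups", call. = FALSE)
  }
  if (any(table(group) < 2)) {
    stop("levene_test(): every group needs at least 2 values", call. = FALSE)
  }
  ctr <- tapply(values, group, if (center == "mean") mean else stats::median)
  dev <- abs(values - ctr[group])
  # a perfectly separated deviation set is a legitimate (extreme) outcome;
  # silence lm's perfect-fit warning rather than refusing the answer
  fit <- suppressWarnings(stats::anova(stats::lm(dev ~ group)))
  structure(list(W = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]),
                 p = fit$`Pr(>F)`[1], center = center),
            class = "levene_result")
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf("Levene's test (%s-centered): W(%d, %d) = %.4f, p = %.4g\n",
              x$center, x$df[1], x$df[2], x$W, x$p))
  invisible(x)
}

#' Effect size r from a t statistic
#'
#' `r = sqrt(t^2 / (t^2 + df))`: sign-insensitive, in `[0, 1)`, strictly
#' increasing in `|t|`. By the conventional benchmarks, r of about 0.1, 0.3
#' and 0.5 mark small, medium and large effects.
#'
#' @param t t statistic (any sign).
#' @param df Degrees of freedom, >= 1.
#' @return Effect size in `[0, 1)`.
#' @export
#' @examples
#' effect_size_r(8.143, 13)  # 0.914 at 3 decimals
effect_size_r <- function(t, df) {
  if (any(df < 1)) stop("effect_size_r(): df must be >= 1", call. = FALSE)
  sqrt(t^2 / (t^2 + df))
}

# truncate (not round) to d decimals, as printed effect sizes often are
truncate_dp <- function(x, d) trunc(x * 10^d) / 10^d

#' Paired t-test of first vs. last trial
#'
#' Paired (dependent-samples) t-test on per-participant pattern counts at
#' the first and last trial, with the effect size r derived from the t
#' statistic. The differences are taken as `first - last`, so a positive t
#' means the pattern became rarer over the trials.
#'
#' @param first,last Numeric vectors of equal length `n >= 2`, paired by
#'   participant.
#' @return List of class `paired_test_result` with `t`, `df` (`n - 1`),
#'   `p` (two-sided), `r`, and `mean_first`, `sem_first`, `mean_last`,
#'   `sem_last`.
#' @export
paired_first_last <- function(first, last) {
  n <- length(first)
  if (length(last) != n || n < 2) {
    stop("paired_first_last(): first/last must be equal length, n >= 2",
         call. = FALSE)
  }
  d <- first - last
  if (stats::sd(d) == 0) {
    stop("paired_first_last(): zero variance of the paired differences; ",
         "t statistic undefined", call. = FALSE)
  }
  tt <- stats::t.test(first, last, paired = TRUE)
  structure(list(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    r = effect_size_r(unname(tt$statistic), unname(tt$parameter)),
    mean_first = mean(first), sem_first = stats::sd(first) / sqrt(n),
    mean_last = mean(last), sem_last = stats::sd(last) / sqrt(n),
    n = n), class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: t(%d) = %.3f, p = %.4g, r = %.4f\n  first %.2f +/- %.2f, last %.2f +/- %.2f (M +/- SEM, n = %d)\n",
    x$df, x$t, x$p, x$r, x$mean_first, x$sem_first, x$mean_last, x$sem_last,
    x$n))
  invisible(x)
}

#' One-way two-group ANOVA
#'
#' Fixed-effects one-way ANOVA between two groups, reported in the classic
#' df / Sum Sq / Mean Sq / F / p table layout. For two groups, F equals the
#' square of the pooled-variance independent-samples t statistic.
#'
#' @param values Numeric vector of observations.
#' @param group Two-level factor/character vector, each level with >= 2
#'   values.
#' @return Tibble with rows `between` and `within`: columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p` (within-row F and p are `NA`).
#' @export
#' @examples
#' anova_two_group(c(1, 2, 3, 4, 5, 6), rep(c("BC", "MC"), each = 3))
anova_two_group <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) != 2) {
    stop("anova_two_group(): exactly 2 groups required", call. = FALSE)
  }
  if (any(table(group) < 2)) {
    stop("anova_two_group(): every group needs at least 2 values",
         call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("anova_two_group(): degenerate data (no variance at all); F undefined",
         call. = FALSE)
  }
  fit <- stats::anova(stats::lm(values ~ group))
  tibble::tibble(
    term = c("between", "within"),
    df = fit$Df,
    sum_sq = fit$`Sum Sq`,
    mean_sq = fit$`Mean Sq`,
    F = c(fit$`F value`[1], NA_real_),
    p = c(fit$`Pr(>F)`[1], NA_real_)
  )
}

#' Full statistical battery over tracked patterns
#'
#' Runs, for each tracked pattern, the within-group paired first-vs-last
#' trial t-tests (per novice group) and the between-group one-way ANOVAs of
#' per-participant slopes and centered intercepts, plus Levene's
#' equal-variance screens. Groups named in `exclude_groups` (by default the
#' expert group, too small for inference) contribute descriptive means only.
#'
#' @param series Dense series tibble from [build_series()], restricted to
#'   the patterns of interest.
#' @param trends Trend-fit tibble from [fit_trends()] on the same series.
#' @param exclude_groups Groups excluded from inference (default `"EXP"`).
#' @param alpha Significance level for the `significant` flags (default 0.05).
#' @param holm Apply a Holm correction across each family of p-values
#'   (default `FALSE`; no correction).
#' @return List with tibbles `paired` (pattern x group: means/SEMs at first
#'   and last trial, t, df, p, r, r_3dp_trunc, significant), `anova`
#'   (pattern x measure(slope/intercept): term, df, SS, MS, F, p,
#'   significant), and `levene` (pattern x measure: W, df, p).
#' @export
pattern_stats <- function(series, trends, exclude_groups = "EXP",
                          alpha = 0.05, holm = FALSE) {
  infer <- series |>
    dplyr::filter(!.data$group %in% exclude_groups)
  first_trial <- min(series$trial)
  last_trial <- max(series$trial)

  paired <- infer |>
    dplyr::filter(.data$trial %in% c(first_trial, last_trial)) |>
    dplyr::group_by(.data$pattern, .data$group) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df, id_cols = "participant",
                                 names_from = "trial",
                                 values_from = "count")
      f <- wide[[as.character(first_trial)]]
      l <- wide[[as.character(last_trial)]]
      res <- tryCatch(paired_first_last(f, l), error = function(e) NULL)
      if (is.null(res)) {
        tibble::tibble(mean_first = mean(f), sem_first = stats::sd(f) / sqrt(length(f)),
                       mean_last = mean(l), sem_last = stats::sd(l) / sqrt(length(l)),
                       t = NA_real_, df = NA_integer_, p = NA_real_,
                       r = NA_real_)
      } else {
        tibble::tibble(mean_first = res$mean_first, sem_first = res$sem_first,
                       mean_last = res$mean_last, sem_last = res$sem_last,
                       t = res$t, df = as.integer(res$df), p = res$p,
                       r = res$r)
      }
    }) |>
    dplyr::ungroup()

  # descriptive rows for excluded groups (no test)
  excl <- series |>
    dplyr::filter(.data$group %in% exclude_groups,
                  .data$trial %in% c(first_trial, last_trial))
  if (nrow(excl) > 0) {
  descr <- excl |>
    dplyr::group_by(.data$pattern, .data$group, .data$trial) |>
    dplyr::summarise(m = mean(.data$count),
                     s = if (dplyr::n() > 1)
                           stats::sd(.data$count) / sqrt(dplyr::n())
                         else NA_real_,
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trial", values_from = c("m", "s")) |>
    dplyr::rename(mean_first = paste0("m_", first_trial),
                  sem_first = paste0("s_", first_trial),
                  mean_last = paste0("m_", last_trial),
                  sem_last = paste0("s_", last_trial)) |>
    dplyr::mutate(t = NA_real_, df = NA_integer_, p = NA_real_, r = NA_real_)
  paired <- dplyr::bind_rows(paired, descr)
  }

  if (holm && any(!is.na(paired$p))) {
    paired$p[!is.na(paired$p)] <- stats::p.adjust(paired$p[!is.na(paired$p)],
                                                  method = "holm")
  }
  paired <- paired |>
    dplyr::mutate(r_3dp_trunc = truncate_dp(.data$r, 3),
                  significant = !is.na(.data$p) & .data$p < alpha) |>
    dplyr::arrange(.data$pattern, .data$group)

  tr_infer <- trends |>
    dplyr::filter(!.data$group %in% exclude_groups) |>
    tidyr::pivot_longer(cols = c("slope", "intercept"),
                        names_to = "measure", values_to = "value")

  anova_tbl <- tr_infer |>
    dplyr::group_by(.data$pattern, .data$measure) |>
    dplyr::group_modify(function(df, key) {
      gm <- mean(df$value)   # before mutate: tb has a column named df
      tb <- tryCatch(anova_two_group(df$value, df$group),
                     error = function(e) tibble::tibble(
                       term = "between", df = NA_integer_, sum_sq = NA_real_,
                       mean_sq = NA_real_, F = NA_real_, p = NA_real_))
      dplyr::mutate(tb, global_mean = gm)
    }) |>
    dplyr::ungroup()
  if (holm) {
    sel <- anova_tbl$term == "between"
    anova_tbl$p[sel] <- stats::p.adjust(anova_tbl$p[sel], method = "holm")
  }
  anova_tbl$significant <- !is.na(anova_tbl$p) & anova_tbl$p < alpha

  levene_tbl <- tr_infer |>
    dplyr::group_by(.data$pattern, .data$measure) |>
    dplyr::group_modify(function(df, key) {
      lv <- tryCatch(levene_test(df$value, df$group),
                     error = function(e) NULL)
      if (is.null(lv)) {
        tibble::tibble(W = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                       p = NA_real_, equal_variances = NA)
      } else {
        tibble::tibble(W = lv$W, df1 = lv$df[1], df2 = lv$df[2], p = lv$p,
                       equal_variances = lv$p > alpha)
      }
    }) |>
    dplyr::ungroup()

  list(paired = paired, anova = anova_tbl, levene = levene_tbl,
       alpha = alpha, first_trial = first_trial, last_trial = last_trial)
}
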