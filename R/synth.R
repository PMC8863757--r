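#' First-order Markov kernel over the AOI alphabet
#'
#' Transition kernel of the scanpath chain on collapsed strings: rows are
#' stochastic and the diagonal is zero, because a collapsed dwell string can
#' never repeat a letter adjacently.
#'
#' @param transition Square matrix with AOI letters as dimnames; rows must
#'   sum to 1 (tolerance 1e-12) with a zero diagonal.
#' @param start Start distribution over the letters; default the kernel's
#'   stationary distribution.
#' @return Object of class `markov_kernel` with elements `alphabet`,
#'   `transition`, `start`.
#' @export
markov_kernel <- function(transition, start = NULL) {
  stopifnot(is.matrix(transition), nrow(transition) == ncol(transition))
  ab <- rownames(transition)
  if (is.null(ab) || !identical(ab, colnames(transition))) {
    stop("markov_kernel(): transition needs matching row/col letter names",
         call. = FALSE)
  }
  if (any(abs(rowSums(transition) - 1) > 1e-12)) {
    stop("markov_kernel(): rows must sum to 1", call. = FALSE)
  }
  if (any(diag(transition) != 0)) {
    stop("markov_kernel(): diagonal must be zero (collapsed strings cannot ",
         "repeat a letter adjacently)", call. = FALSE)
  }
  if (is.null(start)) {
    start <- stationary_distribution(transition)
  } else {
    stopifnot(length(start) == length(ab), abs(sum(start) - 1) < 1e-9)
    start <- stats::setNames(as.numeric(start), ab)
  }
  structure(list(alphabet = ab, transition = transition, start = start),
            class = "markov_kernel")
}

#' Stationary distribution of a transition matrix
#'
#' Solves pi P = pi, sum(pi) = 1 by the left-eigenvector of `P`.
#'
#' @param transition Row-stochastic matrix.
#' @return Named numeric probability vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(transition))
}

#' @export
print.markov_kernel <- function(x, ...) {
  cat("<markov_kernel> alphabet:", paste(x$alphabet, collapse = ""), "\n")
  print(round(x$transition, 3))
  invisible(x)
}

#' Expected k-mer relative frequencies of a scanpath chain
#'
#' Under stationarity, a pattern `w = w1 w2 ... wk` occurs in a window with
#' probability `pi(w1) * prod(P(w_i -> w_{i+1}))`; since every window has
#' the same total probability mass, these are also the expected relative
#' frequencies for long strings.
#'
#' @param kernel A [markov_kernel()].
#' @param k Pattern length.
#' @return Named numeric vector over all collapsed patterns of length `k`
#'   (sums to 1).
#' @export
expected_kmer_freq <- function(kernel, k) {
  pats <- enumerate_patterns(kernel$alphabet, k, collapsed = TRUE)
  pi0 <- stationary_distribution(kernel$transition)
  pr <- vapply(pats, function(p) {
    ch <- strsplit(p, "")[[1]]
    prob <- pi0[ch[1]]
    for (i in seq_len(length(ch) - 1)) {
      prob <- prob * kernel$transition[ch[i], ch[i + 1]]
    }
    unname(prob)
  }, numeric(1))
  pr / sum(pr)
}

#' Mix novice and expert kernels along a saturating learning curve
#'
#' Convex combination with expert weight `w(t) = 1 - exp(-lambda * (t - 1))`:
#' trial 1 is the pure novice kernel, and with increasing trials the mixture
#' saturates toward the expert kernel — an exponential learning curve in
#' which between-trial change shrinks over time. `lambda = 0` freezes the
#' novice kernel (no learning).
#'
#' @param novice,expert [markov_kernel()]s sharing one alphabet.
#' @param t Trial index (1-based).
#' @param lambda Learning rate, >= 0 per trial.
#' @return The mixed [markov_kernel()].
#' @export
mix_kernel <- function(novice, expert, t, lambda) {
  if (lambda < 0) stop("mix_kernel(): lambda must be >= 0", call. = FALSE)
  if (!identical(novice$alphabet, expert$alphabet)) {
    stop("mix_kernel(): kernels must share one alphabet", call. = FALSE)
  }
  w <- 1 - exp(-lambda * (t - 1))
  markov_kernel((1 - w) * novice$transition + w * expert$transition,
                start = (1 - w) * novice$start + w * expert$start)
}

#' Sample one trial string from a scanpath chain
#'
#' Letters follow the chain (start distribution, then transitions); dwell
#' durations are lognormal draws in ms and timestamps cumulate. The zero
#' diagonal guarantees the output is already collapsed.
#'
#' @param kernel A [markov_kernel()].
#' @param length Number of dwells, >= 1.
#' @param dwell_meanlog,dwell_sdlog Lognormal parameters of the per-dwell
#'   duration in ms (defaults `log(280)` and `0.4`).
#' @return Tibble with columns `start_ms`, `duration_ms`, `label` — one row
#'   per dwell, ingest-compatible once participant/trial columns are added.
#' @export
sample_trial <- function(kernel, length, dwell_meanlog = log(280),
                         dwell_sdlog = 0.4) {
  stopifnot(length >= 1)
  ab <- kernel$alphabet
  letters_out <- character(length)
  letters_out[1] <- sample(ab, 1, prob = kernel$start)
  for (i in seq_len(length - 1)) {
    letters_out[i + 1] <- sample(ab, 1,
                                 prob = kernel$transition[letters_out[i], ])
  }
  dur <- stats::rlnorm(length, dwell_meanlog, dwell_sdlog)
  tibble::tibble(start_ms = cumsum(c(0, dur[-length])),
                 duration_ms = dur, label = letters_out)
}

#' Default study kernels
#'
#' Two scanpath kernels over the letters A (building area), B (bricks) and
#' C (manual) chosen to reproduce the qualitative expertise phenomenology:
#' the expert kernel strongly favors A-B alternation (dominant BABA/ABAB
#' patterns, manual almost unused), while the novice kernel routes through
#' the manual (high ACB / ACAC mass).
#'
#' @return List with elements `novice` and `expert`, both [markov_kernel()]s.
#' @export
default_kernels <- function() {
  ab <- c("A", "B", "C")
  expert <- matrix(c(0, 0.92, 0.08,
                     0.92, 0, 0.08,
                     0.50, 0.50, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(ab, ab))
  novice <- matrix(c(0, 0.30, 0.70,
                     0.70, 0, 0.30,
                     0.45, 0.55, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(ab, ab))
  list(novice = markov_kernel(novice), expert = markov_kernel(expert))
}

#' Specification of a synthetic cohort
#'
#' The default mirrors a two-stimulus assembly-learning study: two novice
#' groups of 14 participants (simple "BC" and complex "MC" stimulus) plus an
#' expert group of 2, each completing 8 trials — 240 gaze sequences in
#' total. Novices learn along an exponential saturation curve (BC faster
#' than MC); experts sit on the expert kernel for every trial (plateau).
#' Collapsed string length per trial is Poisson with a mean that mixes from
#' the novice mean toward the shorter expert mean with the same learning
#' weight.
#'
#' @param groups List of group specs: each
#'   `list(name =, n_participants =, lambda =, expert_start = FALSE)`;
#'   `expert_start = TRUE` makes every trial use the expert kernel.
#' @param n_trials Number of trials per participant, >= 2 (default 8).
#' @param novice_kernel,expert_kernel [markov_kernel()]s; default
#'   [default_kernels()].
#' @param novice_len,expert_len Mean collapsed string length (dwells per
#'   trial) at the two ends of the learning curve (defaults 70 and 40).
#' @param dwell_meanlog,dwell_sdlog Lognormal dwell-duration parameters, ms.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(groups = list(
                         list(name = "NOV BC", n_participants = 14,
                              lambda = 0.40),
                         list(name = "NOV MC", n_participants = 14,
                              lambda = 0.25),
                         list(name = "EXP", n_participants = 2, lambda = 0,
                              expert_start = TRUE)),
                       n_trials = 8,
                       novice_kernel = default_kernels()$novice,
                       expert_kernel = default_kernels()$expert,
                       novice_len = 70, expert_len = 40,
                       dwell_meanlog = log(280), dwell_sdlog = 0.4) {
  stopifnot(n_trials >= 2, length(groups) >= 1)
  for (g in groups) {
    stopifnot(g$n_participants >= 1, g$lambda >= 0)
  }
  structure(list(groups = groups, n_trials = n_trials,
                 novice_kernel = novice_kernel, expert_kernel = expert_kernel,
                 novice_len = novice_len, expert_len = expert_len,
                 dwell_meanlog = dwell_meanlog, dwell_sdlog = dwell_sdlog),
            class = "synth_spec")
}

#' Generate a synthetic multi-trial cohort
#'
#' Samples, for every participant and trial, one collapsed scanpath from the
#' trial's mixed kernel (see [mix_kernel()]). A single seed governs all
#' sampling; per-participant substreams are derived deterministically from
#' it, so the cohort is reproducible and participants are independent.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer master seed.
#' @return List with `fixations` (canonical labeled fixation tibble:
#'   participant, group, trial, start_ms, duration_ms, x, y, label) and
#'   `truth` (list: the spec parameters, seed, per-group lambda, and for
#'   each group x trial the expected k-mer relative frequencies of the mixed
#'   kernel for k = 2 and 4).
#' @export
#' @examples
#' cohort <- generate_cohort(synth_spec(groups = list(
#'   list(name = "NOV BC", n_participants = 2, lambda = 0.4)),
#'   n_trials = 3), seed = 1)
#' nrow(dplyr::distinct(cohort$fixations, participant, trial))  # 6
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  out <- list()
  pid <- 0
  for (g in spec$groups) {
    expert_all <- isTRUE(g$expert_start)
    for (i in seq_len(g$n_participants)) {
      pid <- pid + 1
      part_id <- sprintf("P%02d", pid)
      # deterministic 31-bit substream per participant
      set.seed((seed * 1009 + pid * 7919) %% 2147483647)
      for (t in seq_len(spec$n_trials)) {
        kern <- if (expert_all) spec$expert_kernel else
          mix_kernel(spec$novice_kernel, spec$expert_kernel, t, g$lambda)
        w <- if (expert_all) 1 else 1 - exp(-g$lambda * (t - 1))
        len_mean <- (1 - w) * spec$novice_len + w * spec$expert_len
        len <- max(1L, stats::rpois(1, len_mean))
        tr <- sample_trial(kern, len, spec$dwell_meanlog, spec$dwell_sdlog)
        out[[length(out) + 1]] <- tibble::tibble(
          participant = part_id, group = g$name, trial = t,
          start_ms = tr$start_ms, duration_ms = tr$duration_ms,
          x = NA_real_, y = NA_real_, label = tr$label)
      }
    }
  }
  fixations <- dplyr::bind_rows(out)

  truth <- list(
    seed = seed,
    n_trials = spec$n_trials,
    groups = lapply(spec$groups, function(g) {
      expert_all <- isTRUE(g$expert_start)
      per_trial <- lapply(seq_len(spec$n_trials), function(t) {
        kern <- if (expert_all) spec$expert_kernel else
          mix_kernel(spec$novice_kernel, spec$expert_kernel, t, g$lambda)
        list(trial = t,
             transition = kern$transition,
             expected_rel_freq = list(k2 = expected_kmer_freq(kern, 2),
                                      k4 = expected_kmer_freq(kern, 4)))
      })
      list(name = g$name, n_participants = g$n_participants,
           lambda = g$lambda, expert_start = expert_all,
           per_trial = per_trial)
    }),
    novice_kernel = spec$novice_kernel$transition,
    expert_kernel = spec$expert_kernel$transition)

  list(fixations = fixations, truth = truth)
}
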