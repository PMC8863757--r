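test_that("markov_kernel validates stochastic rows and the zero diagonal", {
  ab <- c("A", "B")
  good <- matrix(c(0, 1, 1, 0), 2, dimnames = list(ab, ab))
  k <- markov_kernel(good)
  expect_s3_class(k, "markov_kernel")
  expect_equal(sum(k$start), 1)

  bad_rows <- matrix(c(0, 0.5, 1, 0), 2, byrow = TRUE,
                     dimnames = list(ab, ab))
  expect_error(markov_kernel(bad_rows), "sum to 1")
  bad_diag <- matrix(c(0.5, 0.5, 1, 0), 2, byrow = TRUE,
                     dimnames = list(ab, ab))
  expect_error(markov_kernel(bad_diag), "diagonal")
})

test_that("stationary distribution satisfies pi P = pi", {
  kern <- default_kernels()
  for (k in kern) {
    pi0 <- stationary_distribution(k$transition)
    expect_equal(sum(pi0), 1, tolerance = 1e-12)
    expect_equal(as.numeric(pi0 %*% k$transition), as.numeric(pi0),
                 tolerance = 1e-12)
  }
})

test_that("kernel mixing follows the saturating learning curve", {
  kern <- default_kernels()
  # trial 1: pure novice, any rate
  m1 <- mix_kernel(kern$novice, kern$expert, t = 1, lambda = 0.7)
  expect_equal(m1$transition, kern$novice$transition)
  # lambda 0: novice forever
  m0 <- mix_kernel(kern$novice, kern$expert, t = 8, lambda = 0)
  expect_equal(m0$transition, kern$novice$transition)
  # large lambda, trial 8: within 1e-6 of the expert kernel
  m8 <- mix_kernel(kern$novice, kern$expert, t = 8, lambda = 5)
  expect_lt(max(abs(m8$transition - kern$expert$transition)), 1e-6)
  expect_error(mix_kernel(kern$novice, kern$expert, 2, -0.1), "lambda")
})

test_that("sample_trial follows the chain and is already collapsed", {
  ab <- c("A", "B")
  alt <- markov_kernel(matrix(c(0, 1, 1, 0), 2, dimnames = list(ab, ab)),
                       start = c(1, 0))
  set.seed(1)
  tr <- sample_trial(alt, 9)
  expect_equal(paste(tr$label, collapse = ""), "ABABABABA")
  expect_equal(count_kmers("ABABABABA", 4), c(ABAB = 3L, BABA = 3L))

  set.seed(2)
  one <- sample_trial(alt, 1)
  expect_equal(one$label, "A")

  # timestamps cumulate the durations
  expect_equal(tr$start_ms, cumsum(c(0, tr$duration_ms[-9])))

  # fixed seed reproduces the draw exactly
  kern <- default_kernels()$novice
  set.seed(99); a <- sample_trial(kern, 50)
  set.seed(99); b <- sample_trial(kern, 50)
  expect_identical(a, b)
  # no adjacent repeats ever
  expect_false(any(a$label[-1] == a$label[-50]))
})

test_that("cohort bookkeeping: default spec yields 30 participants x 8 trials", {
  cohort <- generate_cohort(synth_spec(), seed = 4)
  seqs <- dplyr::distinct(cohort$fixations, participant, group, trial)
  expect_equal(nrow(seqs), 240)
  expect_equal(length(unique(seqs$participant)), 30)
  expect_equal(sort(unique(seqs$trial)), 1:8)
  expect_equal(as.integer(table(seqs$group)[c("EXP", "NOV BC", "NOV MC")]),
               c(16L, 112L, 112L))

  small <- generate_cohort(synth_spec(groups = list(
    list(name = "G", n_participants = 1, lambda = 0.4)), n_trials = 2),
    seed = 1)
  expect_equal(nrow(dplyr::distinct(small$fixations, participant, trial)), 2)

  # same seed: identical output; different seed: different strings
  a <- generate_cohort(synth_spec(), seed = 7)
  b <- generate_cohort(synth_spec(), seed = 7)
  expect_identical(a$fixations, b$fixations)
  c_ <- generate_cohort(synth_spec(), seed = 8)
  expect_false(identical(a$fixations$label, c_$fixations$label))
})

test_that("empirical 2-mer frequencies match chain expectations on long trials", {
  kern <- default_kernels()$expert
  set.seed(12)
  n_trials <- 120
  len <- 400
  counts <- integer(0)
  tot <- list()
  for (i in seq_len(n_trials)) {
    s <- paste(sample_trial(kern, len)$label, collapse = "")
    cc <- count_kmers(s, 2)
    for (p in names(cc)) tot[[p]] <- (tot[[p]] %||% 0L) + cc[[p]]
  }
  emp <- unlist(tot)
  emp <- emp / sum(emp)
  expect_val <- expected_kmer_freq(kern, 2)
  # Monte-Carlo agreement: 3 binomial SEs on each pattern
  n_windows <- n_trials * (len - 1)
  for (p in names(expect_val)) {
    se <- sqrt(expect_val[[p]] * (1 - expect_val[[p]]) / n_windows)
    obs <- if (p %in% names(emp)) emp[[p]] else 0
    # binomial SE understates the variance of correlated windows slightly;
    # small absolute cushion on top of the 3-SE band
    expect_lt(abs(obs - expect_val[[p]]), 3 * se + 0.002)
  }
})

test_that("lambda = 0 cohorts show slopes centered on zero", {
  kern <- default_kernels()
  spec <- synth_spec(groups = list(
    list(name = "NOV", n_participants = 14, lambda = 0)), n_trials = 8)
  slopes <- c()
  for (seed in 1:6) {
    cohort <- generate_cohort(spec, seed = seed)
    km <- kmer_table(dwell_strings(collapse_dwells(cohort$fixations)), k = 4)
    s <- build_series(km, patterns = "BABA")
    slopes <- c(slopes, fit_trends(s)$slope)
  }
  # mean slope across 84 exchangeable-trial participants is near zero
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)) + 0.05)
  # and not systematically signed
  expect_gt(mean(slopes > 0), 0.2)
  expect_lt(mean(slopes > 0), 0.8)
})
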