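test_that("count_kmers enumerates overlapping windows", {
  expect_equal(count_kmers("ABABAB", 2), c(AB = 3L, BA = 2L))
  expect_equal(count_kmers("ACB", 3), c(ACB = 1L))
  expect_equal(length(count_kmers("AB", 3)), 0)      # no windows
  expect_equal(count_kmers("ABACBA", 1), c(A = 3L, B = 2L, C = 1L))
  expect_error(count_kmers("ABC", 0), "k must be")
})

test_that("count_kmers matches the brute-force window oracle on random strings", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_collapsed(sample(0:30, 1))
    k <- sample(1:6, 1)
    expect_identical(count_kmers(s, k), oracle_kmers(s, k))
  }
})

test_that("k-mer totals and the k=1/k=2 equivalences to dwell and transition counts hold", {
  set.seed(5)
  fx <- dplyr::bind_rows(lapply(1:4, function(t) {
    labeled_trial(sample(c("A", "B", "C"), 25, replace = TRUE), trial = t)
  }))
  dw <- collapse_dwells(fx)
  strings <- dwell_strings(dw)
  km <- kmer_table(strings, k = c(1, 2))
  m <- trial_metrics(fx)
  for (t in 1:4) {
    k1 <- km[km$k == 1 & km$trial == t, ]
    dwl <- m$dwell[m$dwell$trial == t, ]
    expect_equal(
      stats::setNames(k1$count[order(k1$pattern)], sort(k1$pattern)),
      stats::setNames(dwl$dwell_count[order(dwl$letter)], sort(dwl$letter)))
    k2 <- km[km$k == 2 & km$trial == t, ]
    tr <- m$transition[m$transition$trial == t, ]
    expect_equal(
      stats::setNames(k2$count[order(k2$pattern)], sort(k2$pattern)),
      stats::setNames(tr$count[order(tr$transition)], sort(tr$transition)))
    # window total: L - k + 1
    L <- nchar(strings$string[strings$trial == t])
    expect_equal(sum(k1$count), L)
    expect_equal(sum(k2$count), L - 1L)
  }
})

test_that("relative frequencies implement mean-count normalization and sum to 1", {
  # single trial: counts 4, 4, 2 -> 0.4, 0.4, 0.2
  km <- tibble::tibble(participant = "p1", group = "G", trial = 1L, k = 3L,
                       pattern = c("ACB", "BAB", "CAC"), count = c(4L, 4L, 2L))
  rf <- relative_frequency(km)
  expect_equal(stats::setNames(rf$rel_freq, rf$pattern)[c("ACB", "BAB", "CAC")],
               c(ACB = 0.4, BAB = 0.4, CAC = 0.2))

  # single pattern -> 1.0
  km2 <- km[1, ]
  expect_equal(relative_frequency(km2)$rel_freq, 1.0)

  # two trials {X:2, Y:0} and {X:0, Y:2}: means 1 and 1 -> 0.5 each
  km3 <- tibble::tibble(participant = "p1", group = "G", trial = c(1L, 2L),
                        k = 1L, pattern = c("X", "Y"), count = c(2L, 2L))
  rf3 <- relative_frequency(km3)
  expect_equal(rf3$rel_freq, c(0.5, 0.5))
  expect_equal(rf3$mean_count, c(1, 1))
})

test_that("relative frequencies sum to 1 within every group and k on random cohorts", {
  set.seed(20)
  fx <- dplyr::bind_rows(lapply(1:3, function(p) {
    dplyr::bind_rows(lapply(1:4, function(t) {
      labeled_trial(sample(c("A", "B", "C", "W"), 30, replace = TRUE),
                    participant = paste0("p", p),
                    group = if (p < 3) "G1" else "G2", trial = t)
    }))
  }))
  km <- kmer_table(dwell_strings(collapse_dwells(fx)), k = c(1, 2, 3, 4, 6))
  rf <- relative_frequency(km)
  sums <- tapply(rf$rel_freq, interaction(rf$group, rf$k), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # per-participant mode sums to 1 as well
  rfp <- relative_frequency(km, by = "participant")
  sums_p <- tapply(rfp$rel_freq, interaction(rfp$participant, rfp$k), sum)
  expect_true(all(abs(sums_p - 1) < 1e-12))
})

test_that("relevance filter is strictly greater-than the threshold", {
  v <- c(X = 0.5, Y = 0.495, Z = 0.005)
  expect_equal(relevant_patterns(v), c("X", "Y"))
  expect_equal(relevant_patterns(c(X = 0.01)), character(0))  # strict
  expect_equal(relevant_patterns(stats::setNames(numeric(0), character(0))),
               character(0))
  rf <- tibble::tibble(group = "G", k = 2L, pattern = c("AB", "BA"),
                       mean_count = c(99, 1), rel_freq = c(0.99, 0.01),
                       sem = NA_real_)
  expect_equal(relevant_patterns(rf)$pattern, "AB")
})

test_that("possible-pattern counts match exhaustive enumeration", {
  expect_equal(count_possible_patterns(4, 4), 108)
  expect_equal(count_possible_patterns(4, 1), 4)
  expect_equal(count_possible_patterns(4, 2), 12)
  expect_equal(count_possible_patterns(4, 3, collapsed = FALSE), 64)
  expect_equal(count_possible_patterns(1, 3), 0)   # 1 letter cannot avoid repeats

  ab4 <- c("A", "B", "C", "W")
  for (n in 2:4) {
    for (k in 1:5) {
      ab <- ab4[seq_len(n)]
      expect_equal(length(enumerate_patterns(ab, k)),
                   count_possible_patterns(n, k))
      expect_equal(length(enumerate_patterns(ab, k, collapsed = FALSE)),
                   count_possible_patterns(n, k, collapsed = FALSE))
    }
  }
  # enumerated collapsed patterns never repeat a letter adjacently
  pats <- enumerate_patterns(ab4, 4)
  expect_false(any(grepl("(.)\\1", pats)))
})

test_that("alphabet restriction drops excluded letters and renormalizes", {
  km <- tibble::tibble(participant = "p1", group = "G", trial = 1L, k = 2L,
                       pattern = c("AB", "AW", "BA"), count = c(3L, 1L, 2L))
  out <- restrict_alphabet(km, c("A", "B"))
  expect_equal(out$pattern, c("AB", "BA"))
  expect_equal(out$count, c(3L, 2L))

  rf <- relative_frequency(km)
  rfr <- restrict_alphabet(rf, c("A", "B"))
  expect_equal(sum(rfr$rel_freq), 1)
  expect_false(any(grepl("W", rfr$pattern)))

  expect_identical(restrict_alphabet(km, c("A", "B", "W")), km)
  expect_equal(nrow(restrict_alphabet(km, "C")), 0)
  expect_error(restrict_alphabet(km, character(0)), "at least one")
})
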