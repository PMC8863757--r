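test_that("Levene's test: identical deviation sets give W = 0, p = 1", {
  lv <- levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(lv$W, 0)
  expect_equal(lv$p, 1)

  # unequal spread is detected (ANOVA on absolute deviations by hand:
  # deviations {0,0,0,0} vs {5,5,5,5} -> between-group SS > 0)
  lv2 <- levene_test(c(0, 0, 0, 0, -5, 5, -5, 5),
                     rep(c("a", "b"), each = 4))
  expect_gt(lv2$W, 0)
  expect_lt(lv2$p, 0.05)

  expect_error(levene_test(1:4, rep("a", 4)), "2 groups")
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")), "at least 2 values")
})

test_that("Levene agrees with the car implementation (mean- and median-centered)", {
  skip_if_not_installed("car")
  set.seed(17)
  for (i in 1:10) {
    v <- c(rnorm(8, 0, 1), rnorm(10, 0, 3))
    g <- rep(c("a", "b"), c(8, 10))
    for (ctr in c("mean", "median")) {
      ours <- levene_test(v, g, center = ctr)
      ref <- car::leveneTest(v, factor(g), center = ctr)
      expect_equal(ours$W, ref$`F value`[1], tolerance = 1e-10)
      expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    }
  }
})

test_that("paired first-vs-last test matches the closed form", {
  res <- paired_first_last(c(1, 2, 3, 4), c(2, 4, 3, 3))
  # d = (-1, -2, 0, 1): mean -0.5, sd sqrt(5/3), t = -0.5/(sd/2)
  expect_equal(res$t, -0.5 / (sqrt(5 / 3) / 2), tolerance = 1e-10)
  expect_equal(res$t, -0.7746, tolerance = 1e-4)
  expect_equal(res$df, 3)
  expect_equal(res$r, effect_size_r(res$t, 3))
  expect_equal(res$mean_first, 2.5)

  # all differences equal -> zero variance -> degenerate
  expect_error(paired_first_last(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_first_last(1:3, 1:2), "equal length")
})

test_that("paired test is antisymmetric in first/last", {
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(14, 10, 3)
    b <- rnorm(14, 6, 3)
    f <- paired_first_last(a, b)
    r <- paired_first_last(b, a)
    expect_equal(r$t, -f$t, tolerance = 1e-12)
    expect_equal(r$p, f$p, tolerance = 1e-12)
    expect_equal(r$r, f$r, tolerance = 1e-12)
  }
})

test_that("effect size r follows sqrt(t^2 / (t^2 + df)) and its limits", {
  expect_equal(effect_size_r(8.143, 13), sqrt(8.143^2 / (8.143^2 + 13)))
  expect_equal(trunc(effect_size_r(8.143, 13) * 1000) / 1000, 0.914)
  expect_equal(effect_size_r(0, 13), 0)
  expect_equal(effect_size_r(-6.679, 13), effect_size_r(6.679, 13))
  expect_error(effect_size_r(1, 0), "df")

  # monotone in |t|, bounded in [0, 1)
  ts <- seq(0, 50, by = 0.5)
  rs <- effect_size_r(ts, 13)
  expect_true(all(diff(rs) > 0))
  expect_true(all(rs >= 0 & rs < 1))
  expect_gt(effect_size_r(1e6, 13), 0.999999)
})

test_that("two-group ANOVA reproduces hand-computed sums of squares", {
  a <- anova_two_group(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$sum_sq, c(13.5, 4))
  expect_equal(a$df, c(1L, 4L))
  expect_equal(a$F[1], 13.5)

  # identical groups: F = 0
  a2 <- anova_two_group(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(a2$F[1], 0)

  expect_error(anova_two_group(rep(1, 6), rep(c("g1", "g2"), each = 3)),
               "degenerate")
  expect_error(anova_two_group(1:9, rep(c("a", "b", "c"), each = 3)),
               "exactly 2")
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(29)
  for (i in 1:20) {
    v <- c(rnorm(14, 1), rnorm(14, 2))
    g <- rep(c("g1", "g2"), each = 14)
    a <- anova_two_group(v, g)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(a$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p[1], tt$p.value, tolerance = 1e-10)
    # SS decomposition
    expect_equal(sum(a$sum_sq), sum((v - mean(v))^2), tolerance = 1e-10)
  }
})

test_that("pattern_stats assembles paired, ANOVA and Levene tables with flags", {
  set.seed(37)
  mk <- function(p, g, base, slope) {
    tibble::tibble(participant = p, group = g, pattern = "BABA",
                   trial = 1:8,
                   count = pmax(0, round(base + slope * (1:8) + rnorm(8, 0, 1))))
  }
  series <- dplyr::bind_rows(
    lapply(1:6, function(i) mk(sprintf("bc%d", i), "NOV BC", 1, 1.2)),
    lapply(1:6, function(i) mk(sprintf("mc%d", i), "NOV MC", 1, 0.4)),
    lapply(1:2, function(i) mk(sprintf("ex%d", i), "EXP", 11, 0)))
  trends <- fit_trends(series)
  st <- pattern_stats(series, trends)

  expect_setequal(st$paired$group, c("NOV BC", "NOV MC", "EXP"))
  # experts are descriptive only
  exp_row <- st$paired[st$paired$group == "EXP", ]
  expect_true(is.na(exp_row$t))
  expect_false(is.na(exp_row$mean_first))
  # novice rows carry a full test with df = n - 1
  bc <- st$paired[st$paired$group == "NOV BC", ]
  expect_equal(bc$df, 5L)
  expect_equal(bc$r, effect_size_r(bc$t, bc$df))
  expect_equal(bc$r_3dp_trunc, trunc(bc$r * 1000) / 1000)

  # ANOVA table covers slope and intercept with between/within rows
  expect_setequal(unique(st$anova$measure), c("slope", "intercept"))
  expect_equal(sum(st$anova$term == "between"), 2)
  # slope difference 1.2 vs 0.4 with sd ~0.1 should be significant
  slope_row <- st$anova[st$anova$measure == "slope" &
                        st$anova$term == "between", ]
  expect_lt(slope_row$p, 0.05)
  expect_true(slope_row$significant)

  expect_equal(nrow(st$levene), 2)
  expect_true(all(st$levene$p >= 0 & st$levene$p <= 1))
})
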