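# shared fixtures and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

fixation_row <- function(participant = "p1", group = "NOV BC", trial = 1L,
                         start = 0, dur = 100, x = NA_real_, y = NA_real_,
                         label = NA_character_) {
  tibble::tibble(participant = participant, group = group,
                 trial = as.integer(trial), start_ms = start,
                 duration_ms = dur, x = x, y = y, label = label)
}

labeled_trial <- function(labels, durations = rep(100, length(labels)),
                          participant = "p1", group = "NOV BC", trial = 1L) {
  starts <- cumsum(c(0, durations[-length(durations)]))
  fixation_row(participant, group, trial, starts, durations,
               label = labels)
}

# random collapsed string (no adjacent repeats)
random_collapsed <- function(len, alphabet = c("A", "B", "C", "W")) {
  if (len == 0) return("")
  s <- character(len)
  s[1] <- sample(alphabet, 1)
  for (i in seq_len(len - 1)) {
    s[i + 1] <- sample(setdiff(alphabet, s[i]), 1)
  }
  paste(s, collapse = "")
}

# brute-force k-mer oracle: explicit loop over windows, table at the end
oracle_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(stats::setNames(integer(0), character(0)))
  out <- character(0)
  for (i in 1:(L - k + 1)) out <- c(out, substr(s, i, i + k - 1))
  tt <- table(out)
  stats::setNames(as.integer(tt), names(tt))
}

# normal-equation OLS oracle on centered regressor
oracle_ols <- function(trial, count) {
  xc <- trial - mean(trial)
  X <- cbind(1, xc)
  beta <- solve(t(X) %*% X, t(X) %*% count)
  list(intercept = beta[1], slope = beta[2])
}

# simple 2-region scheme used across AOI tests
test_scheme <- function() {
  aoi_scheme(list(
    list(letter = "A", name = "building area",
         geometry = list(type = "rect", x0 = 0, y0 = 0, x1 = 100, y1 = 100)),
    list(letter = "B", name = "bricks",
         geometry = list(type = "rect", x0 = 100, y0 = 0, x1 = 200, y1 = 100)),
    list(letter = "C", name = "manual",
         geometry = list(type = "polygon",
                         x = c(0, 100, 100, 0), y = c(100, 100, 200, 200)))
  ))
}

# gaze samples at 60 Hz around given positions
samples_at <- function(xs, ys, t0 = 0, hz = 60, valid = TRUE) {
  n <- length(xs)
  tibble::tibble(t = t0 + (seq_len(n) - 1) * 1000 / hz,
                 x = xs, y = ys, valid = rep_len(valid, n))
}
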