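---
title: "Methods: k-mer analysis of gaze sequences across repeated trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer analysis of gaze sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazekmer)
```

## From fixations to strings

The unit of observation is a *trial*: one participant performing the task
once while their gaze is recorded. Fixations — intervals where gaze is
nearly stationary — arrive either pre-detected from the vendor's event
detector or are detected here with the I-VT algorithm: point-to-point
velocities between consecutive valid samples are compared against a
threshold (default 40 deg/s when a pixels-per-degree conversion is given,
otherwise 40 input-units/s), maximal sub-threshold runs form candidate
fixations, and candidates shorter than 50 ms are dropped. A fixation's
duration is the last-minus-first member sample time plus one (median)
sample period, so an n-sample fixation at 60 Hz lasts n/60 s. Invalid
samples always split candidates: a blink never bridges two fixations,
which is conservative but avoids inventing continuity. No merge step for
nearby fixations is applied — vendor detectors differ in how (and whether)
they merge, and silently guessing a rule would change dwell counts, so the
package leaves fixations exactly as detected.

Each fixation is mapped to an area of interest (AOI) coded as a single
uppercase letter, with a whitespace letter (default `W`) for fixations
falling into no region. Rectangles use half-open membership
(`[x0, x1) x [y0, y1)`), so a shared edge belongs to exactly one region;
polygons use even-odd membership with boundary points counted inside.
Overlaps are resolved by scheme order: the first listed region wins. This
makes labeling total and deterministic for any scheme.

Consecutive fixations on the same AOI form a *dwell* and collapse to one
letter, so a trial becomes a string in which no letter neighbors itself.
Collapsing is idempotent and conserves both total fixation time and
fixation count. The mean fixation duration reported in the traditional
metrics includes whitespace fixations by default (`include_whitespace =
FALSE` restricts it), because the fixation stream, not the AOI scheme,
defines what a fixation is.

## k-mer counting and relative frequency

All overlapping windows of length k are counted at stride 1, giving
`L - k + 1` windows for a string of collapsed length L. On collapsed
strings the k = 1 table *is* the per-AOI dwell count and the k = 2 table
*is* the ordered AOI transition table, which the test suite verifies
exactly; larger k capture behavior the traditional metrics cannot.

The relative frequency of a pattern averages its count per trial within a
participant (trials where the pattern is absent contribute zero), averages
those per-participant means within the group, and normalizes by the sum
over all same-k patterns. Both group-level and per-participant outputs are
available, since group reports are the usual end product but participant
level values are what the trend machinery consumes. Relevance uses a
strict `> 0.01` cutoff; the strictness matters only for patterns sitting
exactly on the threshold, which the filter excludes.

The possible pattern space over `n` letters has `n^k` members unrestricted
and `n * (n - 1)^(k - 1)` members when adjacent repeats are excluded — the
only kind a collapsed string can contain (for 4 AOIs and k = 4: 108).
`count_possible_patterns()` reports these closed forms and
`enumerate_patterns()` generates the space explicitly; the two are checked
against each other exhaustively for alphabets up to 4 letters and k up to 5.

## Learning trends and statistics

For each participant and tracked pattern, the per-trial counts (zeros
included) are regressed on the centered trial index `trial - mean(trial)`
by ordinary least squares. Centering makes the intercept the fitted value
at the mean trial, which under OLS equals the participant's mean count —
so intercepts compare *average pattern occurrence* between groups while
slopes compare *learning rate* in counts per trial. Raw counts, not
relative frequencies, are the trended quantity: count scales are what
first-vs-last trial comparisons and group curves report. Trials are used
as an equally spaced 1-based regressor, unweighted and with no trials
dropped; with only eight points, weighting schemes have little support and
would add a free choice.

The battery, run on the novice groups (the expert group is descriptive
only — two participants cannot support inference):

* **Levene's test**, classic mean-centered form: a one-way ANOVA of the
  absolute deviations from group means. The median-centered Brown-Forsythe
  variant is available via `center = "median"`. The classic form is the
  default because it is what the name "Levene's test" conventionally
  denotes.
* **Paired t-test** of each participant's count at the first vs. the last
  trial, differences taken as `first - last` (positive t = pattern became
  rarer). The effect size is `r = sqrt(t^2 / (t^2 + df))`, sign-insensitive
  and strictly increasing in |t|; reports carry 4 decimals plus a
  3-decimal *truncated* companion column, since printed effect sizes in
  the literature are often truncated rather than rounded.
* **Two-group one-way ANOVA** of the per-participant slopes and centered
  intercepts, reported in the classic df/SS/MS/F/p layout; for two groups
  F equals the squared pooled-variance t, which the tests verify
  numerically.

All p-values are two-sided with α = 0.05 by default. No multiple-testing
correction is applied by default — the tracked pattern set is small and
chosen a priori — but `holm = TRUE` applies a Holm correction across each
family for users who prefer it.

## The synthetic cohort generator

`generate_cohort()` emulates a two-stimulus assembly-learning study. Each
trial string is drawn from a first-order Markov chain on the collapsed
alphabet (zero diagonal, so output is collapsed by construction). Two
kernels define the behavioral poles:

* **expert**: strong building-area/bricks alternation
  (P(A→B) = P(B→A) = 0.92), manual nearly unused — dominant `ABAB`/`BABA`
  mass;
* **novice**: gaze routed through the manual (P(A→C) = 0.7), giving high
  `ACB`/`ACAC` mass.

Novices at trial t follow the convex mixture with expert weight
`w(t) = 1 - exp(-lambda * (t - 1))`: pure novice at trial 1, saturating
toward the expert kernel — an exponential learning curve whose
between-trial change shrinks over time. Defaults: 14 participants per
novice group (the group size at which a paired test has df = 13), 2
experts who sit on the expert kernel in every trial (plateau), 8 trials,
`lambda` 0.40 for the simple-stimulus group and 0.25 for the
complex-stimulus group (slower learning under the harder stimulus).
Collapsed string length is Poisson with mean mixing 70 (novice) to 40
(expert) under the same `w(t)` — experts are more efficient, so their
sequences are shorter — and dwell durations are lognormal
(meanlog = log(280 ms), sdlog = 0.4), a right-skewed distribution typical
of dwell times. One master seed drives everything; per-participant
substreams are derived deterministically from it, so cohorts are exactly
reproducible and participants are independent.

The ground-truth record carries the per-trial mixed kernels and their
exact expected k-mer relative frequencies (stationary distribution times
transition products), which the tests compare against long-run empirical
frequencies.

What the generator does **not** emulate: raw gaze kinematics (no saccade
trajectories — detector tests use hand-built sample streams), within-trial
non-stationarity, higher-order sequential dependence, individual
differences in learning rate, task times or use errors. Passing tests on
synthetic cohorts therefore demonstrate that the machinery recovers known
dynamics from collapsed letter sequences; they cannot certify fixation
detection or AOI geometry choices on any particular real recording.

## Numerical choices and degenerate inputs

* Velocity is Euclidean displacement over Δt between consecutive valid
  samples, unsmoothed by default; an optional centered moving average
  (`smooth_window`) is exposed for noisy trackers.
* Fewer than two valid samples yields an empty fixation set, not an error;
  non-monotone timestamps are a data error.
* Empty strings, empty k-mer maps, and all-zero count totals propagate as
  empty results rather than NaN; relative-frequency normalization never
  divides by zero.
* A paired test with zero-variance differences and an ANOVA with no
  variance at all are *degenerate-data errors* — the statistics are
  undefined and the package refuses rather than returning infinities. In
  the batch report (`pattern_stats()`) such cells degrade to `NA` rows so
  one degenerate pattern cannot abort a whole report.
* Stationary distributions come from the left eigenvector of the
  transition matrix at eigenvalue 1, renormalized to sum to 1.
* SEM is the sample SD over sqrt(n); with n = 1 it is reported as `NA`,
  not 0.

## Problem sizes in the test suite

The suite verifies k-mer counting against a brute-force window enumerator
on 1,000 random collapsed strings (length ≤ 30, alphabets of 2-4 letters,
k ≤ 6), OLS trends against the normal equations on 150 random 8-trial
series, and parameter recovery on 20 simulated cohorts of 14 participants
each (learning-direction sign recovery), 6 no-learning cohorts (slopes
centered on zero), and 10 expert cohorts (first-vs-last plateau). These
sizes give stable pass/fail behavior at fixed seeds while keeping a full
run under a minute on one CPU.

## Known limitations

* First-order Markov simulation cannot express patterns whose prevalence
  exceeds what chained 2-mer statistics imply; real experts may be more
  stereotyped than the chain.
* AOI geometry is user-supplied; the package validates but cannot infer it.
* Linear trends are the only learning-curve model fitted; saturating
  dynamics are approximated by their average slope over the trial window.
* The relevance filter operates on group-averaged frequencies, so a
  pattern dominant in one participant but absent elsewhere can fall below
  the cutoff.
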