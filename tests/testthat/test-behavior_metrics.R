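mk_trial <- function(trial = 1, condition = "coherent", direction = "cw",
                     strength = 5, onset = 4, onsets = "", offsets = "") {
  data.frame(trial = trial, condition = condition, direction = direction,
             strength = strength, motion_onset = onset,
             motion_offset = onset + 20, vection_onsets = onsets,
             vection_offsets = offsets, stringsAsFactors = FALSE)
}

test_that("trial metrics: presence, first-onset latency, total duration", {
  # onset 6.3 s and offset 18.9 s after motion onset -> latency 6.3, duration 12.6
  tab <- mk_trial(onset = 4, onsets = "10.3", offsets = "22.9")
  m <- derive_trial_metrics(tab)
  expect_true(m$presence)
  expect_equal(m$onset_latency, 6.3)
  expect_equal(m$duration, 12.6)

  # no presses
  m0 <- derive_trial_metrics(mk_trial(strength = 0))
  expect_false(m0$presence)
  expect_true(is.na(m0$onset_latency))
  expect_equal(m0$duration, 0)

  # two intervals 5-8 s and 12-16 s after motion onset
  m2 <- derive_trial_metrics(mk_trial(onset = 3, onsets = "8;15",
                                      offsets = "11;19"))
  expect_equal(m2$onset_latency, 5)
  expect_equal(m2$duration, 7)
})

test_that("open intervals close at trial end; orphan offsets are dropped", {
  # onset at 10 s into a trial starting at 4 -> closes at 4 + 20 + 10 = 34
  m <- derive_trial_metrics(mk_trial(onset = 4, onsets = "14", offsets = ""))
  expect_equal(m$duration, 20)
  expect_warning(m2 <- derive_trial_metrics(mk_trial(onsets = "",
                                                     offsets = "12",
                                                     strength = 0)),
                 "offset before any onset")
  expect_false(m2$presence)
})

test_that("participant summaries take medians over qualifying trials", {
  tab <- rbind(
    mk_trial(1, onsets = "8", offsets = "16", strength = 6),    # lat 4
    mk_trial(2, onsets = "10", offsets = "20", strength = 7),   # lat 6
    mk_trial(3, onsets = "12", offsets = "24", strength = 4),   # lat 8
    mk_trial(4, strength = 0))
  m <- derive_trial_metrics(tab)
  s <- summarize_participant(m, "coherent")
  expect_equal(s$presence_count, 3)
  expect_equal(s$onset_latency, 6)      # median over present trials only
  expect_equal(s$duration, 10)
  expect_equal(s$strength, 5)           # median over all trials: 0,4,6,7

  # zero present trials: latency and duration are missing
  s0 <- summarize_participant(derive_trial_metrics(mk_trial(strength = 0)),
                              "coherent")
  expect_equal(s0$presence_count, 0)
  expect_true(is.na(s0$onset_latency))
  expect_equal(s0$strength, 0)
})

test_that("rank-sum comparison: symmetry, effect size, and exact agreement", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)
  expect_equal(same$r, 0)

  # r = Z / sqrt(N)
  cg <- compare_groups(rnorm(30, 1), rnorm(35))
  expect_equal(cg$r, cg$Z / sqrt(65))
  expect_equal(cg$p_adjusted, min(1, 8 * cg$p))

  # antisymmetry under label swap
  set.seed(1)
  x <- rnorm(12); y <- rnorm(10, 0.5)
  expect_equal(compare_groups(x, y)$Z, -compare_groups(y, x)$Z)
  expect_true(abs(compare_groups(x, y)$r) <= 1)

  # normal approximation vs exhaustive enumeration on small groups
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  ex <- ranksum_exact_p(a, b)
  expect_equal(ex, 0.1, tolerance = 1e-12)  # 2 * 1/choose(6,3)
  expect_equal(wilcox.test(a, b, exact = TRUE)$p.value, ex)
  appr <- compare_groups(a, b)
  expect_lt(abs(appr$p - ex), 0.06)
  # and with ties, against the approximation quality bound
  set.seed(2)
  for (i in 1:5) {
    g1 <- sample(1:6, 7, replace = TRUE)
    g2 <- sample(2:8, 7, replace = TRUE)
    expect_lt(abs(compare_groups(g1, g2)$p - ranksum_exact_p(g1, g2)), 0.08)
  }
})

test_that("Z and p match the standard rank-sum implementation", {
  set.seed(31)
  x <- round(rnorm(20, 5, 2), 1); y <- round(rnorm(25, 6, 2), 1)
  cg <- compare_groups(x, y)
  ref <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(cg$p, ref$p.value, tolerance = 1e-10)
})

test_that("group table covers every measure in both conditions", {
  set.seed(8)
  summaries <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(subject = sprintf("s%02d", i),
               group = ifelse(i <= 6, "left", "right"),
               condition = rep(c("coherent", "incoherent"), each = 1),
               n_trials = 50,
               presence_count = c(rbinom(1, 50, 0.95), rbinom(1, 50, 0.08)),
               onset_latency = c(rlnorm(1, log(6), 0.4), rlnorm(1, log(12), 0.3)),
               duration = c(rlnorm(1, log(13), 0.3), rlnorm(1, log(4.5), 0.5)),
               strength = c(sample(3:8, 1), sample(0:2, 1)))
  }))
  tab <- behavior_group_table(summaries, m = 8)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$measure),
                  c("presence_count", "onset_latency", "duration", "strength"))
  expect_true(all(tab$p_adjusted >= tab$p - 1e-12))
  expect_true(all(abs(tab$r) <= 1))
})
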