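zero_noise_cohort <- function(...) {
  cohort_spec(noise = list(pink_amplitude = 0, white_sd = 0, shared_mix = 0),
              subject_scale_sdlog = 0, attenuation_sdlog = 0,
              artifact_rates = list(blink = 0, range = 0), ...)
}

test_that("zero-noise epochs equal the template projection exactly", {
  tpl <- erp_template_spec()
  ch <- zero_noise_cohort(trials_per_condition = 2, condition_attenuation = 1,
                          group_effect_ratio = 1, seed = 3)
  ep <- simulate_subject_epochs(tpl, ch, "s1", "left", seed = 3,
                                layout = the_layout)
  # attenuation 1: both conditions identical, every epoch identical
  expect_equal(ep$data[1, , ], ep$data[3, , ])  # coherent vs incoherent
  expect_equal(ep$data[1, , ], ep$data[2, , ])
  # peak near 190 ms at Cz with the template amplitude
  czi <- match("Cz", ep$channels)
  ti <- match(190, ep$times)
  expect_equal(ep$data[1, czi, ti], -6 + 5 * exp(-(190 - 280)^2 / (2 * 15^2)),
               tolerance = 1e-6)
  # EOG channels carry no template signal
  expect_equal(max(abs(ep$data[, match("VEOG", ep$channels), ])), 0)
})

test_that("planted attenuation and group ratio appear in the window means", {
  tpl <- erp_template_spec()
  ch <- zero_noise_cohort(trials_per_condition = 1,
                          condition_attenuation = 0.7,
                          group_effect_ratio = 1.5, seed = 1)
  wm <- function(group, cond, window) {
    ep <- simulate_subject_epochs(tpl, ch, "s", group, seed = 1,
                                  layout = the_layout)
    window_mean_amplitude(average_condition(ep, cond), window)
  }
  # right-handers: coherent/incoherent ratio = 0.7 at the early centre
  expect_equal(unname(wm("right", "coherent", erp_windows$early)["Cz"] /
                        wm("right", "incoherent", erp_windows$early)["Cz"]),
               0.7, tolerance = 1e-10)
  # left-handers' early condition difference is 1.5x the right-handers'
  # (up to the vanishing tail of the late component inside the early window)
  dl <- wm("left", "coherent", erp_windows$early)["Cz"] -
    wm("left", "incoherent", erp_windows$early)["Cz"]
  dr <- wm("right", "coherent", erp_windows$early)["Cz"] -
    wm("right", "incoherent", erp_windows$early)["Cz"]
  expect_equal(unname(dl / dr), 1.5, tolerance = 1e-3)
  # the late window carries no handedness effect
  dl2 <- wm("left", "coherent", erp_windows$late)["CPz"] -
    wm("left", "incoherent", erp_windows$late)["CPz"]
  dr2 <- wm("right", "coherent", erp_windows$late)["CPz"] -
    wm("right", "incoherent", erp_windows$late)["CPz"]
  expect_equal(unname(dl2 / dr2), 1, tolerance = 1e-2)
})

test_that("noisy condition averages recover the template within MC tolerance", {
  tpl <- erp_template_spec()
  ch <- cohort_spec(trials_per_condition = 50, condition_attenuation = 1,
                    group_effect_ratio = 1,
                    noise = list(pink_amplitude = 4, white_sd = 4,
                                 shared_mix = 0.3),
                    subject_scale_sdlog = 0, attenuation_sdlog = 0, seed = 7)
  ep <- simulate_subject_epochs(tpl, ch, "s", "right", seed = 7,
                                layout = the_layout)
  clean <- simulate_subject_epochs(tpl, zero_noise_cohort(
    trials_per_condition = 1, condition_attenuation = 1,
    group_effect_ratio = 1, seed = 7), "s", "right", seed = 7,
    layout = the_layout)
  avg <- average_condition(ep, "coherent")$data
  template <- clean$data[1, , ]
  # per-sample noise SD ~ sqrt(4^2 + 4^2); average of 50 epochs
  tol <- 4 * sqrt(2) * sqrt(4^2 + 4^2) / sqrt(50)
  expect_lt(max(abs(avg - template)), tol)
})

test_that("cohort simulation is deterministic and correctly sized", {
  tpl <- erp_template_spec()
  ch <- cohort_spec(n_left = 3, n_right = 2, trials_per_condition = 2,
                    seed = 9)
  co1 <- simulate_cohort(tpl, ch, layout = the_layout)
  co2 <- simulate_cohort(tpl, ch, layout = the_layout)
  expect_equal(length(co1$subjects), 5)
  expect_equal(co1$groups, c("left", "left", "left", "right", "right"))
  expect_identical(co1$subjects[[4]]$data, co2$subjects[[4]]$data)
  expect_identical(co1$truth, co2$truth)
  expect_equal(dim(co1$subjects[[1]]$data)[1], 4)  # 2 per condition
})

test_that("artifact injection matches its labels and rates", {
  tpl <- erp_template_spec()
  ch <- cohort_spec(trials_per_condition = 50, seed = 2)
  ep <- simulate_subject_epochs(tpl, ch, "s", "right", seed = 2,
                                layout = the_layout)
  # rate 0 leaves the data untouched
  clean <- inject_artifacts(ep, list(blink = 0, range = 0), seed = 5)
  expect_identical(clean$epochs$data, ep$data)
  expect_equal(nrow(clean$labels), 0)

  inj <- inject_artifacts(ep, list(blink = 0.2, range = 0), seed = 5)
  n_blink <- sum(inj$labels$type == "blink")
  expect_gt(n_blink, qbinom(0.005, 100, 0.2))
  expect_lt(n_blink, qbinom(0.995, 100, 0.2))
  # a blink drives the Fp1 windowed SD far beyond 35 uV
  e <- inj$labels$epoch[1]
  fp1 <- match("Fp1", ep$channels)
  delta <- inj$epochs$data[e, fp1, ] - ep$data[e, fp1, ]
  sds <- vapply(seq(1, 401, by = 50),
                function(s) sd(inj$epochs$data[e, fp1, s:(s + 199)]),
                numeric(1))
  expect_gt(max(sds), 35)
  expect_equal(max(abs(delta)), 150, tolerance = 1)
})

test_that("behavioural simulation honours presence and latency settings", {
  bs <- behavior_spec(presence_prob = c(coherent = 1, incoherent = 0))
  none <- simulate_behavior(bs, 20, "incoherent", 0.5, seed = 1)
  expect_true(all(none$strength == 0))
  expect_true(all(none$vection_onsets == ""))
  m <- derive_trial_metrics(none)
  expect_false(any(m$presence))
  expect_equal(median(m$strength), 0)

  # degenerate latency: every latency exactly 6 s
  bs2 <- behavior_spec(presence_prob = c(coherent = 1, incoherent = 0),
                       latency_median = c(coherent = 6, incoherent = 12),
                       latency_sdlog = c(coherent = 0, incoherent = 0))
  all6 <- simulate_behavior(bs2, 10, "coherent", 0.5, seed = 2)
  m6 <- derive_trial_metrics(all6)
  expect_true(all(m6$presence))
  expect_equal(m6$onset_latency, rep(6, 10))
})

test_that("strength couples to attenuation at the configured rank level", {
  bs <- behavior_spec(strength_brain_coupling = 0.8)
  n <- 57
  set.seed(33)
  u <- rank(rnorm(n)) / (n + 1)
  med_strength <- vapply(seq_len(n), function(i) {
    trials <- simulate_behavior(bs, 50, "coherent", u[i], seed = 100 + i)
    median(derive_trial_metrics(trials)$strength)
  }, numeric(1))
  rho <- spearman_correlation(u, med_strength)$rho
  expect_gt(rho, 0.6)
  expect_lt(rho, 0.95)
})
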