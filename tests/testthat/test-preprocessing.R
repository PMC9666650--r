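test_that("notch attenuates line frequencies and the passband is preserved", {
  srate <- 1000
  t <- seq(0, 4, by = 1 / srate)
  mk_rec <- function(x) new_recording(matrix(x, 1), srate, "Cz")
  amp_at <- function(x, f) {
    mid <- x[1000:3000]
    sqrt(2 * mean(mid^2))
  }
  f50 <- apply_filters(mk_rec(sin(2 * pi * 50 * t)))
  expect_lt(amp_at(f50$data[1, ], 50), 10^(-30 / 20))  # >= 30 dB down
  f100 <- apply_filters(mk_rec(sin(2 * pi * 100 * t)))
  expect_lt(amp_at(f100$data[1, ], 100), 10^(-30 / 20))
  f10 <- apply_filters(mk_rec(sin(2 * pi * 10 * t)))
  expect_equal(amp_at(f10$data[1, ], 10), 1, tolerance = 0.05)
  f40 <- apply_filters(mk_rec(sin(2 * pi * 40 * t)))  # above 30 Hz lowpass
  expect_lt(amp_at(f40$data[1, ], 40), 0.1)
})

test_that("filtering is linear and zero in gives zero out", {
  srate <- 1000
  t <- seq(0, 2, by = 1 / srate)
  a <- sin(2 * pi * 7 * t)
  b <- cos(2 * pi * 13 * t)
  mk <- function(x) new_recording(matrix(x, 1), srate, "Cz")
  fa <- apply_filters(mk(a))$data
  fb <- apply_filters(mk(b))$data
  fab <- apply_filters(mk(a + b))$data
  expect_equal(fab, fa + fb, tolerance = 1e-10)
  expect_equal(max(abs(apply_filters(mk(numeric(length(t))))$data)), 0)
  expect_error(apply_filters(mk(a), lowpass = 600),
               class = "vection_validation_error")
})

test_that("common-average re-referencing zeroes the scalp mean, skips EOG", {
  data <- rbind(c(4, 8), c(2, 0), c(100, 100))
  rec <- new_recording(data, 1000, c("Cz", "Pz", "VEOG"))
  out <- rereference_common_average(rec)
  expect_equal(out$data["Cz", ], c(1, 4))   # (a - b)/2
  expect_equal(out$data["Pz", ], c(-1, -4))
  expect_equal(out$data["VEOG", ], c(100, 100))  # EOG untouched
  expect_equal(colMeans(out$data[c("Cz", "Pz"), ]), c(0, 0))
  expect_equal(out$reference, "common_average")
  # idempotent
  expect_equal(rereference_common_average(out)$data, out$data)
})

test_that("epoching extracts one 600-sample epoch per motion onset", {
  rec <- make_tiny_recording()
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data), c(2, 4, 600))
  expect_equal(range(ep$times), c(-200, 399))
  expect_equal(ep$labels$condition, c("coherent", "incoherent"))
  # epoch content matches the raw slice
  expect_equal(ep$data[1, 2, ], unname(rec$data[2, 301:900]))

  # event too close to the start is dropped with a warning
  ev <- data.frame(sample_index = c(10L, 1500L), kind = "motion_onset",
                   condition = "coherent", direction = "cw")
  rec2 <- make_tiny_recording(events = ev)
  expect_warning(ep2 <- epoch_recording(rec2), "dropping")
  expect_equal(dim(ep2$data)[1], 1)

  ev3 <- data.frame(sample_index = 5L, kind = "motion_onset",
                    condition = "coherent", direction = "cw")
  expect_error(suppressWarnings(epoch_recording(make_tiny_recording(events = ev3))),
               class = "vection_empty_set_error")
})

test_that("baseline correction subtracts the pre-stimulus mean once", {
  ep <- make_flat_epochs(value = 7)
  out <- baseline_correct(ep)
  expect_equal(max(abs(out$data)), 0)
  expect_error(baseline_correct(out), class = "vection_state_error")

  ep2 <- make_flat_epochs(fill = function(e, c) c(rep(3, 200), rep(10, 400)))
  out2 <- baseline_correct(ep2)
  expect_equal(out2$data[1, 1, 300], 7)
  expect_equal(mean(out2$data[2, 3, 1:200]), 0)
})

test_that("sliding-window rejection applies the SD and range rules", {
  # epoch 2: Fp1 window SD ~40 uV but range below 100 -> rejected by rule (a)
  ep <- make_flat_epochs(n_epochs = 3)
  ep$data[2, 1, 101:300] <- rep(c(40, -40), 100)
  # epoch 3: 150 uV spike in Cz -> rejected by rule (b)
  ep$data[3, 3, 400] <- 150
  res <- reject_artifacts(ep)
  expect_equal(which(res$log$rejected), c(2L, 3L))
  expect_equal(res$log$rule[2:3], c("sd", "range"))
  expect_equal(res$log$channel[2:3], c("Fp1", "Cz"))
  expect_equal(dim(res$kept$data)[1], 1)

  # quiet epochs with SD <= 30 and range <= 90 are kept
  ep2 <- make_flat_epochs(n_epochs = 2,
                          fill = function(e, c) 45 * sin(seq(0, 6 * pi, length.out = 600)))
  res2 <- reject_artifacts(ep2)
  expect_false(any(res2$log$rejected))
})

test_that("the SD threshold is a strict inequality at exactly 35 uV", {
  win <- boundary_sd_window()
  ep <- make_flat_epochs(n_epochs = 2)
  ep$data[1, 2, 1:200] <- win            # Fz windowed SD exactly 35 -> kept
  ep$data[2, 2, 1:200] <- win * (1 + 1e-6)  # 35 + epsilon -> rejected
  # neutralise the range rule for this construction
  crit <- rejection_criteria(range_threshold = 1e6)
  res <- reject_artifacts(ep, crit)
  expect_equal(res$log$rejected, c(FALSE, TRUE))
  expect_equal(res$log$rule[2], "sd")
})

test_that("rejection is invariant to epoch order and flags missing channels", {
  set.seed(99)
  ep <- make_flat_epochs(n_epochs = 6,
                         fill = function(e, c) rnorm(600, sd = 5))
  ep$data[4, 1, 200:350] <- ep$data[4, 1, 200:350] + 200
  res <- reject_artifacts(ep)
  perm <- c(3, 1, 6, 4, 2, 5)
  ep_p <- ep
  ep_p$data <- ep$data[perm, , ]
  ep_p$labels <- ep$labels[perm, ]
  res_p <- reject_artifacts(ep_p)
  expect_equal(res_p$log$rejected, res$log$rejected[perm])

  expect_error(reject_artifacts(ep, rejection_criteria(sd_channels = "Nope")),
               class = "vection_validation_error")
})

test_that("rejected epochs match injected ground truth exactly", {
  tpl <- erp_template_spec()
  ch <- cohort_spec(trials_per_condition = 10, seed = 5)
  ep <- simulate_subject_epochs(tpl, ch, "s1", "right", seed = 5,
                                layout = the_layout)
  inj <- inject_artifacts(ep, list(blink = 0.25, range = 0.15), seed = 21)
  res <- reject_artifacts(baseline_correct(inj$epochs))
  expect_gt(nrow(inj$labels), 3)
  expect_equal(which(res$log$rejected), sort(inj$labels$epoch))
})

test_that("participant inclusion requires 30 clean epochs per condition", {
  expect_false(check_participant_inclusion(29, 45))
  expect_true(check_participant_inclusion(50, 50))
  expect_true(check_participant_inclusion(30, 30))  # "fewer than 30"
  expect_equal(check_participant_inclusion(c(29, 31), c(45, 31)),
               c(FALSE, TRUE))
})
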