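#' Epoch sets
#'
#' An `epoch_set` holds segmented EEG as an epochs x channels x time array
#' (microvolts) with a millisecond time axis relative to motion onset,
#' per-epoch labels (condition, direction, subject, group), and state flags
#' recording whether baseline correction and artifact rejection have been
#' applied. Every processing stage appends a structured provenance entry.
#'
#' @param data numeric array, epochs x channels x time.
#' @param times numeric vector, ms relative to motion onset.
#' @param channels character vector of channel names.
#' @param labels data frame with one row per epoch; columns `condition`,
#'   `direction` at minimum.
#' @param srate sampling rate, Hz.
#' @return an `epoch_set`.
#' @export
new_epoch_set <- function(data, times, channels, labels, srate = 1000) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels),
            dim(data)[3] == length(times), dim(data)[1] == nrow(labels))
  structure(list(data = data, times = times, channels = channels,
                 labels = labels, srate = srate,
                 baseline_corrected = FALSE, rejection_applied = FALSE,
                 rejection_log = NULL, provenance = list()),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate))
  invisible(x)
}

add_provenance <- function(obj, stage, params) {
  obj$provenance <- c(obj$provenance, list(list(stage = stage, params = params)))
  obj
}

is_eog_channel <- function(labels) grepl("EOG", labels, ignore.case = TRUE)

# ---------------------------------------------------------------------------
# Filtering
# ---------------------------------------------------------------------------

# Zero-phase application of an odd-length symmetric FIR kernel by FFT
# convolution; the group delay of (L-1)/2 samples is removed exactly.
filt_zero_phase <- function(x, kernel) {
  n <- length(x)
  l <- length(kernel)
  m <- (l - 1L) %/% 2L
  nfft <- stats::nextn(n + l - 1L, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - n))) *
                fft(c(kernel, numeric(nfft - l))), inverse = TRUE)) / nfft
  y[(m + 1L):(m + n)]
}

# Windowed-sinc FIR designs via signal::fir1 (Hamming window). Order is
# chosen from the transition width: N ~ 3.3 * fs / transition.
fir_order <- function(srate, transition) {
  n <- ceiling(3.3 * srate / transition)
  n + n %% 2L  # even order -> odd length, symmetric
}

design_filters <- function(srate, notch, highpass, lowpass,
                           notch_halfwidth = 2.5, lp_transition = 10,
                           notch_transition = 2) {
  nyq <- srate / 2
  if (any(c(notch, lowpass) >= nyq)) {
    stop_vection("filter frequency at or above Nyquist", "vection_validation_error")
  }
  kernels <- list()
  if (!is.null(highpass) && highpass > 0) {
    kernels$highpass <- signal::fir1(fir_order(srate, highpass),
                                     highpass / nyq, type = "high")
  }
  if (!is.null(lowpass)) {
    kernels$lowpass <- signal::fir1(fir_order(srate, lp_transition),
                                    lowpass / nyq, type = "low")
  }
  for (f0 in notch) {
    kernels[[paste0("notch", f0)]] <-
      signal::fir1(fir_order(srate, notch_transition),
                   c(f0 - notch_halfwidth, f0 + notch_halfwidth) / nyq,
                   type = "stop")
  }
  kernels
}

#' Filter a continuous recording
#'
#' Applies, in order: 50 and 100 Hz FIR notch filters (line noise), then a
#' 0.1 Hz high-pass and a 30 Hz low-pass. All filters are linear-phase FIR
#' kernels applied zero-phase (symmetric kernel, exact group-delay removal),
#' so ERP peak latencies are not distorted. Filtering precedes
#' re-referencing.
#'
#' @param rec a [new_recording()] object.
#' @param notch notch centre frequencies, Hz (default `c(50, 100)`).
#' @param highpass high-pass cutoff, Hz (default 0.1; `NULL` to skip).
#' @param lowpass low-pass cutoff, Hz (default 30).
#' @return the filtered recording with a provenance entry.
#' @export
apply_filters <- function(rec, notch = c(50, 100), highpass = 0.1,
                          lowpass = 30) {
  stopifnot(inherits(rec, "recording"))
  if (rec$srate <= 2 * max(c(notch, lowpass, highpass))) {
    stop_vection("sampling rate too low for requested filters",
                 "vection_validation_error")
  }
  kernels <- design_filters(rec$srate, notch, highpass, lowpass)
  for (k in kernels) {
    for (ch in seq_len(nrow(rec$data))) {
      rec$data[ch, ] <- filt_zero_phase(rec$data[ch, ], k)
    }
  }
  add_provenance(rec, "apply_filters",
                 list(notch = notch, highpass = highpass, lowpass = lowpass,
                      orders = vapply(kernels, length, integer(1)) - 1L))
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across scalp EEG channels (EOG
#' channels are excluded from the average and left untouched). Idempotent:
#' applying twice changes nothing beyond a second provenance entry.
#'
#' @param rec a [new_recording()] object.
#' @return re-referenced recording with `reference = "common_average"`.
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  eeg <- !is_eog_channel(rec$channel_labels)
  if (sum(eeg) < 2) {
    stop_vection("need at least 2 EEG channels for common average",
                 "vection_validation_error")
  }
  avg <- colMeans(rec$data[eeg, , drop = FALSE])
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, avg)
  rec$reference <- "common_average"
  add_provenance(rec, "rereference_common_average",
                 list(n_eeg = sum(eeg), excluded = rec$channel_labels[!eeg]))
}

#' Segment a recording into epochs around an event
#'
#' One epoch per event of the requested kind, spanning `[tmin, tmax)` ms
#' relative to the event sample (600 samples for the default -200..+400 ms
#' at 1000 Hz). Events whose window exceeds the recording bounds are dropped
#' with a warning.
#'
#' @param rec a [new_recording()] object with events.
#' @param event_kind event kind to time-lock to (default `"motion_onset"`).
#' @param tmin,tmax epoch bounds in ms (defaults -200 and +400).
#' @return an `epoch_set` with labels copied from the events.
#' @export
epoch_recording <- function(rec, event_kind = "motion_onset",
                            tmin = -200, tmax = 400) {
  stopifnot(inherits(rec, "recording"))
  ev <- rec$events[rec$events$kind == event_kind, , drop = FALSE]
  n_pre <- round(-tmin * rec$srate / 1000)
  n_len <- round((tmax - tmin) * rec$srate / 1000)
  n_samp <- ncol(rec$data)
  start <- ev$sample_index - n_pre
  ok <- start >= 0 & (start + n_len) <= n_samp
  if (any(!ok)) {
    warning(sprintf("dropping %d event(s) whose epoch window exceeds the recording",
                    sum(!ok)))
  }
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) {
    stop_vection("no usable events to epoch", "vection_empty_set_error")
  }
  times <- seq(tmin, by = 1000 / rec$srate, length.out = n_len)
  data <- array(0, c(nrow(ev), nrow(rec$data), n_len))
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$sample_index[i] - n_pre + 1L):(ev$sample_index[i] - n_pre + n_len)
    data[i, , ] <- rec$data[, idx]
  }
  ep <- new_epoch_set(data, times, rec$channel_labels,
                      labels = data.frame(epoch = seq_len(nrow(ev)),
                                          condition = ev$condition,
                                          direction = ev$direction,
                                          stringsAsFactors = FALSE),
                      srate = rec$srate)
  add_provenance(ep, "epoch_recording",
                 list(event_kind = event_kind, tmin = tmin, tmax = tmax,
                      n_epochs = nrow(ev), n_dropped = sum(!ok)))
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and channel, the mean over the 200 ms pre-stimulus
#' interval (times < 0 ms). Errors if already applied.
#'
#' @param epochs an `epoch_set`.
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$baseline_corrected) {
    stop_vection("baseline correction already applied", "vection_state_error")
  }
  base_idx <- which(epochs$times < 0)
  if (!length(base_idx)) {
    stop_vection("no pre-stimulus samples for baseline", "vection_validation_error")
  }
  bl <- rowMeans(epochs$data[, , base_idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs$baseline_corrected <- TRUE
  add_provenance(epochs, "baseline_correct", list(interval = range(epochs$times[base_idx])))
}

#' Artifact-rejection criteria
#'
#' @param window_len sliding-window length, ms (default 200).
#' @param window_step window step, ms (default 50).
#' @param sd_threshold windowed standard-deviation threshold, microvolts
#'   (default 35; strict inequality, unbiased n-1 denominator).
#' @param sd_channels channels the SD rule applies to; default the EOG pair
#'   plus Fp1, Fp2 and Fz.
#' @param range_threshold windowed peak-to-peak threshold, microvolts
#'   (default 100; strict inequality).
#' @param range_channels channels the range rule applies to; default all
#'   scalp EEG channels (EOG excluded).
#' @return a `rejection_criteria` list.
#' @export
rejection_criteria <- function(window_len = 200, window_step = 50,
                               sd_threshold = 35, sd_channels = NULL,
                               range_threshold = 100, range_channels = NULL) {
  stopifnot(window_len > 0, window_step > 0, sd_threshold > 0,
            range_threshold > 0)
  structure(list(window_len = window_len, window_step = window_step,
                 sd_threshold = sd_threshold, sd_channels = sd_channels,
                 range_threshold = range_threshold,
                 range_channels = range_channels),
            class = "rejection_criteria")
}

default_sd_channels <- function(channels) {
  c(channels[is_eog_channel(channels)],
    intersect(c("Fp1", "Fp2", "Fz"), channels))
}

#' Sliding-window artifact rejection
#'
#' Each epoch is scanned with a 200 ms window sliding in 50 ms steps (only
#' full windows are evaluated: offsets 0, 50, ..., epoch length minus window
#' length; 9 windows for a 600 ms epoch). An epoch is rejected if any window
#' has (a) a standard deviation greater than `sd_threshold` in any SD-rule
#' channel, or (b) a signal range (max minus min) greater than
#' `range_threshold` in any range-rule channel. The log records the first
#' triggering window, channel and rule per rejected epoch.
#'
#' @param epochs an `epoch_set`.
#' @param criteria a [rejection_criteria()].
#' @return list with `kept` (`epoch_set` of surviving epochs) and `log`
#'   (data frame: epoch, rejected, rule, channel, window_start_ms).
#' @export
reject_artifacts <- function(epochs, criteria = rejection_criteria()) {
  stopifnot(inherits(epochs, "epoch_set"))
  sd_ch <- criteria$sd_channels %||% default_sd_channels(epochs$channels)
  rng_ch <- criteria$range_channels %||%
    epochs$channels[!is_eog_channel(epochs$channels)]
  missing_ch <- setdiff(sd_ch, epochs$channels)
  if (length(missing_ch)) {
    stop_vection(paste("SD-rule channel absent from data:",
                       paste(missing_ch, collapse = ", ")),
                 "vection_validation_error")
  }
  spms <- epochs$srate / 1000
  wl <- round(criteria$window_len * spms)
  ws <- round(criteria$window_step * spms)
  n_t <- dim(epochs$data)[3]
  starts <- seq(1L, n_t - wl + 1L, by = ws)  # full windows only
  sd_idx <- match(sd_ch, epochs$channels)
  rng_idx <- match(rng_ch, epochs$channels)
  n_ep <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]

  # Flatten to (epoch*channel) x time: column-major order makes row
  # e + (c-1)*n_ep of M equal to epochs$data[e, c, ].
  M <- matrix(epochs$data, n_ep * n_ch, n_t)
  sd_rows <- as.vector(outer(seq_len(n_ep), (sd_idx - 1L) * n_ep, `+`))
  rng_rows <- as.vector(outer(seq_len(n_ep), (rng_idx - 1L) * n_ep, `+`))
  row_max <- function(m) do.call(pmax, asplit(m, 2))
  row_min <- function(m) do.call(pmin, asplit(m, 2))

  log <- data.frame(epoch = seq_len(n_ep), rejected = FALSE,
                    rule = NA_character_, channel = NA_character_,
                    window_start_ms = NA_real_)
  record_hits <- function(viol_mat, chans, rule, s) {
    # viol_mat: n_ep x n_channels-in-scope logical; channel order = scope order
    hit_ep <- which(rowSums(viol_mat) > 0 & !log$rejected)
    for (e in hit_ep) {
      log$rejected[e] <<- TRUE
      log$rule[e] <<- rule
      log$channel[e] <<- chans[which(viol_mat[e, ])[1]]
      log$window_start_ms[e] <<- epochs$times[s]
    }
  }
  for (s in starts) {
    cols <- s:(s + wl - 1L)
    Wsd <- M[sd_rows, cols, drop = FALSE]
    mu <- rowMeans(Wsd)
    ssq <- rowSums(Wsd^2)
    sds <- sqrt(pmax(0, (ssq - wl * mu^2) / (wl - 1)))
    record_hits(matrix(sds > criteria$sd_threshold, n_ep), sd_ch, "sd", s)
    Wr <- M[rng_rows, cols, drop = FALSE]
    rng <- row_max(Wr) - row_min(Wr)
    record_hits(matrix(rng > criteria$range_threshold, n_ep), rng_ch,
                "range", s)
    if (all(log$rejected)) break
  }
  keep <- !log$rejected
  kept <- epochs
  kept$data <- epochs$data[keep, , , drop = FALSE]
  kept$labels <- epochs$labels[keep, , drop = FALSE]
  rownames(kept$labels) <- NULL
  kept$rejection_applied <- TRUE
  kept$rejection_log <- log
  kept <- add_provenance(kept, "reject_artifacts",
                         list(criteria = unclass(criteria),
                              n_in = n_ep, n_kept = sum(keep)))
  list(kept = kept, log = log)
}

#' Participant inclusion rule
#'
#' A participant is excluded from the EEG analyses if fewer than
#' `min_trials` artifact-free epochs were obtained for either the coherent
#' or the incoherent condition. Exactly `min_trials` epochs is sufficient
#' (the rule is "fewer than").
#'
#' @param n_coherent,n_incoherent artifact-free epoch counts (vectorised).
#' @param min_trials minimum per-condition count (default 30).
#' @return logical vector: `TRUE` if included.
#' @export
check_participant_inclusion <- function(n_coherent, n_incoherent,
                                        min_trials = 30) {
  n_coherent >= min_trials & n_incoherent >= min_trials
}
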