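#' ERP averaging and window amplitudes
#'
#' Condition ERPs are pointwise means across a condition's epochs (clockwise
#' and counter-clockwise trials collapsed); difference waves are coherent
#' minus incoherent; window mean amplitudes are per-electrode means over the
#' early (160-220 ms) or late (260-300 ms) analysis window with inclusive
#' bounds.
#'
#' @name erp_analysis
NULL

#' Analysis windows
#' @export
erp_windows <- list(early = c(160, 220), late = c(260, 300))

new_erp_waveform <- function(data, times, n_epochs, label) {
  structure(list(data = data, times = times, n_epochs = n_epochs,
                 label = label),
            class = "erp_waveform")
}

#' Average the epochs of one condition
#'
#' @param epochs an `epoch_set`.
#' @param condition `"coherent"` or `"incoherent"`.
#' @return an `erp_waveform` (channels x time matrix) carrying the
#'   contributing epoch count.
#' @export
average_condition <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- which(epochs$labels$condition == condition)
  if (!length(sel)) {
    stop_vection(paste("no epochs for condition", condition),
                 "vection_empty_set_error")
  }
  avg <- colMeans(epochs$data[sel, , , drop = FALSE])  # mean over epochs
  rownames(avg) <- epochs$channels
  new_erp_waveform(avg, epochs$times, length(sel),
                   list(subject = epochs$labels$subject[sel][1] %||% NA,
                        condition = condition,
                        group = epochs$labels$group[sel][1] %||% NA))
}

#' Coherent-minus-incoherent difference wave
#'
#' @param coh,inc `erp_waveform`s on identical channels and times.
#' @return an `erp_waveform` labelled `"difference"`, carrying both parents'
#'   epoch counts.
#' @export
difference_wave <- function(coh, inc) {
  if (!identical(rownames(coh$data), rownames(inc$data)) ||
      !isTRUE(all.equal(coh$times, inc$times))) {
    stop_vection("difference_wave: mismatched channels or time axes",
                 "vection_validation_error")
  }
  new_erp_waveform(coh$data - inc$data, coh$times,
                   c(coh = coh$n_epochs, inc = inc$n_epochs),
                   list(subject = coh$label$subject, condition = "difference",
                        group = coh$label$group))
}

#' Per-electrode mean amplitude in an analysis window
#'
#' Samples with `start <= t <= end` contribute (inclusive bounds: 61 samples
#' for 160-220 ms at 1000 Hz).
#'
#' @param wave an `erp_waveform`.
#' @param window numeric `c(start, end)` in ms, e.g. `erp_windows$early`.
#' @return named numeric vector of per-electrode mean amplitudes, microvolts.
#' @export
window_mean_amplitude <- function(wave, window) {
  stopifnot(inherits(wave, "erp_waveform"), length(window) == 2)
  idx <- which(wave$times >= window[1] - 1e-9 & wave$times <= window[2] + 1e-9)
  if (!length(idx) || window[1] < min(wave$times) || window[2] > max(wave$times)) {
    stop_vection("window outside epoch time axis", "vection_validation_error")
  }
  rowMeans(wave$data[, idx, drop = FALSE])
}

#' Grand average of subject ERPs
#'
#' Each subject's waveform is weighted equally regardless of its epoch
#' count, matching the subject-level statistics used downstream.
#'
#' @param waves list of `erp_waveform`s on identical channels/times.
#' @return an `erp_waveform`; `n_epochs` is the number of subjects.
#' @export
grand_average <- function(waves) {
  stopifnot(length(waves) >= 1)
  acc <- waves[[1]]$data * 0
  for (w in waves) acc <- acc + w$data
  new_erp_waveform(acc / length(waves), waves[[1]]$times, length(waves),
                   list(subject = "grand", condition = waves[[1]]$label$condition,
                        group = "all"))
}

#' Per-subject condition window amplitudes for a set of epoch sets
#'
#' Convenience wrapper: averages each subject's epochs per condition and
#' extracts window mean amplitudes, yielding the subjects x electrodes
#' matrices consumed by the cluster-based permutation tests.
#'
#' @param epoch_sets list of per-subject `epoch_set`s.
#' @param window numeric `c(start, end)` ms.
#' @return list with matrices `coherent` and `incoherent` (subjects x
#'   electrodes, scalp channels only) and `subjects`, `groups`.
#' @export
subject_window_amplitudes <- function(epoch_sets, window) {
  scalp <- NULL
  res <- lapply(conditions_ok, function(cond) {
    t(vapply(epoch_sets, function(ep) {
      wv <- average_condition(ep, cond)
      amp <- window_mean_amplitude(wv, window)
      amp[!is_eog_channel(names(amp))]
    }, numeric(sum(!is_eog_channel(epoch_sets[[1]]$channels)))))
  })
  names(res) <- conditions_ok
  res$subjects <- vapply(epoch_sets, function(ep) ep$labels$subject[1], character(1))
  res$groups <- vapply(epoch_sets, function(ep) ep$labels$group[1], character(1))
  res
}
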