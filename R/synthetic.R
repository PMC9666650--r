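#' Synthetic motion-onset ERP cohorts
#'
#' The generator plants a known spatiotemporal ERP structure into noise so
#' that every downstream stage (preprocessing, window statistics, cluster
#' tests, correlations) can be tested against ground truth. Each epoch is
#'
#'   epoch = template projection (condition- and group-scaled)
#'         + 1/f ("pink") noise + white noise,
#'
#' spanning -200..+399 ms around motion onset at 1000 Hz. The template has
#' two components: an early peak inside 160-220 ms and a later peak inside
#' 260-300 ms with reversed polarity, both with Gaussian spatial topographies
#' over the 2D-projected montage. The coherent condition attenuates the
#' template at the topography centre; left-handers carry a larger early
#' condition difference than right-handers.
#'
#' @name synthetic_data
NULL

#' ERP template specification
#'
#' @param components list of components, each a list with `peak_latency`
#'   (ms), `width` (temporal Gaussian SD, ms), `amplitude` (microvolts at the
#'   topography centre), `center` (channel name), `spread` (spatial Gaussian
#'   SD in 2D-projection units, i.e. radians of polar angle).
#' @param group_effect_component index of the component that carries the
#'   handedness effect (default 1, the early component).
#' @return an `erp_template_spec`.
#' @export
erp_template_spec <- function(components = NULL, group_effect_component = 1L) {
  if (is.null(components)) {
    components <- list(
      list(peak_latency = 190, width = 20, amplitude = -6,
           center = "Cz", spread = 0.45),
      list(peak_latency = 280, width = 15, amplitude = 5,
           center = "CPz", spread = 0.45))
  }
  for (cmp in components) {
    stopifnot(all(c("peak_latency", "width", "amplitude", "center",
                    "spread") %in% names(cmp)))
  }
  structure(list(components = components,
                 group_effect_component = as.integer(group_effect_component)),
            class = "erp_template_spec")
}

#' Cohort specification
#'
#' @param n_left,n_right numbers of left-/right-handed subjects (defaults 28
#'   and 29, the study's final EEG sample).
#' @param trials_per_condition trials per condition per subject (default 50).
#' @param condition_attenuation multiplicative factor applied to the template
#'   at the topography centre in the coherent condition for right-handers
#'   (default 0.7; values < 1 attenuate).
#' @param group_effect_ratio factor by which left-handers' early condition
#'   difference exceeds right-handers' (default 1.6; 1 = no handedness
#'   effect).
#' @param noise list with `pink_amplitude` and `white_sd` (per-sample SD,
#'   microvolts) and `shared_mix` (fraction of pink-noise variance shared
#'   across channels).
#' @param artifact_rates list with per-epoch probabilities `blink`, `range`.
#' @param subject_scale_sdlog SD of the log-normal per-subject amplitude
#'   scale (default 0.15).
#' @param attenuation_sdlog SD of the log-normal per-subject jitter on the
#'   attenuation depth (default 0.25). The same latent susceptibility drives
#'   the brain-behaviour coupling.
#' @param seed master RNG seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_left = 28, n_right = 29, trials_per_condition = 50,
                        condition_attenuation = 0.7, group_effect_ratio = 1.6,
                        noise = list(pink_amplitude = 4, white_sd = 4,
                                     shared_mix = 0.3),
                        artifact_rates = list(blink = 0.05, range = 0.02),
                        subject_scale_sdlog = 0.15, attenuation_sdlog = 0.25,
                        seed = 1L) {
  stopifnot(condition_attenuation > 0, condition_attenuation <= 1,
            group_effect_ratio >= 1, trials_per_condition >= 1)
  stopifnot(all(unlist(artifact_rates) >= 0), all(unlist(artifact_rates) <= 1))
  structure(list(n_left = n_left, n_right = n_right,
                 trials_per_condition = trials_per_condition,
                 condition_attenuation = condition_attenuation,
                 group_effect_ratio = group_effect_ratio, noise = noise,
                 artifact_rates = artifact_rates,
                 subject_scale_sdlog = subject_scale_sdlog,
                 attenuation_sdlog = attenuation_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

synthetic_channels <- function(layout) c(layout$channels, "HEOG", "VEOG")

epoch_time_axis <- function(srate = 1000, tmin = -200, tmax = 400) {
  seq(tmin, tmax - 1000 / srate, by = 1000 / srate)
}

# Spatial Gaussian weights over the 2D-projected montage; EOG channels get 0.
topography_weights <- function(layout, center, spread, channels) {
  if (!center %in% layout$channels) {
    stop_vection(paste("topography centre not in montage:", center),
                 "vection_validation_error")
  }
  c0 <- layout$pos2d[center, ]
  d2 <- (layout$pos2d[, 1] - c0[1])^2 + (layout$pos2d[, 2] - c0[2])^2
  w <- setNames(numeric(length(channels)), channels)
  w[layout$channels] <- exp(-d2 / (2 * spread^2))
  w
}

#' Planted electrode set of a template component
#'
#' Electrodes carrying at least `min_weight` of the component's peak spatial
#' weight; this is the ground-truth set that recovered clusters are compared
#' against.
#'
#' @param template an [erp_template_spec()].
#' @param layout a `sensor_layout`.
#' @param component component index (1 = early, 2 = late by default).
#' @param min_weight weight cutoff (default 0.25).
#' @return character vector of channel names.
#' @export
planted_electrodes <- function(template, layout, component = 1,
                               min_weight = 0.25) {
  cmp <- template$components[[component]]
  w <- topography_weights(layout, cmp$center, cmp$spread, layout$channels)
  names(w)[w >= min_weight]
}

# Noise-free template signal for one condition: channels x time, microvolts.
template_projection <- function(template, layout, channels, times, group,
                                cohort, subject_depth_scale = 1,
                                subject_scale = 1, condition) {
  sig <- matrix(0, length(channels), length(times),
                dimnames = list(channels, NULL))
  base_depth <- 1 - cohort$condition_attenuation
  for (k in seq_along(template$components)) {
    cmp <- template$components[[k]]
    w <- topography_weights(layout, cmp$center, cmp$spread, channels)
    g <- exp(-(times - cmp$peak_latency)^2 / (2 * cmp$width^2))
    depth <- base_depth
    if (k == template$group_effect_component && group == "left") {
      depth <- depth * cohort$group_effect_ratio
    }
    depth <- min(depth * subject_depth_scale, 0.95)
    scale <- if (condition == "coherent") 1 - depth else 1
    sig <- sig + (cmp$amplitude * subject_scale * scale) * outer(w, g)
  }
  sig
}

# Spectrally shaped 1/f noise: white Gaussian spectra multiplied by a
# 1/sqrt(f) amplitude profile, scaled analytically to the target per-sample
# SD. Returns an n_time x n_series matrix.
pink_noise <- function(n_time, n_series, sd_target) {
  if (sd_target == 0 || n_series == 0) return(matrix(0, n_time, n_series))
  w <- matrix(rnorm(n_time * n_series), n_time, n_series)
  spec <- mvfft(w)
  freq <- c(0, pmin(seq_len(n_time - 1), n_time - seq_len(n_time - 1)))
  prof <- c(0, 1 / sqrt(freq[-1]))
  shaped <- Re(mvfft(spec * prof, inverse = TRUE)) / n_time
  shaped * (sd_target / sqrt(mean(prof^2)))
}

#' Simulate one subject's epochs for both conditions
#'
#' @param template an [erp_template_spec()].
#' @param cohort a [cohort_spec()].
#' @param subject_id subject identifier string.
#' @param group `"left"` or `"right"`.
#' @param seed RNG seed for this subject.
#' @param layout a `sensor_layout` (default: the shipped montage).
#' @return an `epoch_set` with both conditions labelled; ground truth
#'   (latent susceptibility, attenuation depths, subject scale) is stored in
#'   `$truth`.
#' @export
simulate_subject_epochs <- function(template, cohort, subject_id = "s01",
                                    group = c("right", "left"), seed = 1L,
                                    layout = NULL) {
  group <- match.arg(group)
  layout <- layout %||% load_montage()
  channels <- synthetic_channels(layout)
  times <- epoch_time_axis()
  n_t <- length(times)
  n_trials <- cohort$trials_per_condition

  set.seed(seed)
  z <- rnorm(1)  # latent vection susceptibility
  subject_scale <- rlnorm(1, 0, cohort$subject_scale_sdlog)
  depth_scale <- exp(cohort$attenuation_sdlog * z)

  n_epochs <- 2L * n_trials
  conds <- rep(conditions_ok, each = n_trials)
  dirs <- rep(rep(directions_ok, length.out = n_trials), 2)
  data <- array(0, c(n_epochs, length(channels), n_t))

  sig <- lapply(conditions_ok, function(cond) {
    template_projection(template, layout, channels, times, group, cohort,
                        subject_depth_scale = depth_scale,
                        subject_scale = subject_scale, condition = cond)
  })
  names(sig) <- conditions_ok

  pink_sd <- cohort$noise$pink_amplitude
  white_sd <- cohort$noise$white_sd
  mix <- cohort$noise$shared_mix %||% 0
  n_ch <- length(channels)
  for (e in seq_len(n_epochs)) {
    epoch <- sig[[conds[e]]]
    if (pink_sd > 0) {
      indep <- t(pink_noise(n_t, n_ch, pink_sd))
      if (mix > 0) {
        shared <- pink_noise(n_t, 1, pink_sd)[, 1]
        indep <- sqrt(1 - mix) * indep +
          sqrt(mix) * matrix(shared, n_ch, n_t, byrow = TRUE)
      }
      epoch <- epoch + indep
    }
    if (white_sd > 0) {
      epoch <- epoch + matrix(rnorm(n_ch * n_t, sd = white_sd), n_ch, n_t)
    }
    data[e, , ] <- epoch
  }

  ep <- new_epoch_set(data, times, channels,
                      labels = data.frame(epoch = seq_len(n_epochs),
                                          condition = conds, direction = dirs,
                                          subject = subject_id, group = group,
                                          stringsAsFactors = FALSE),
                      srate = 1000)
  base_depth <- 1 - cohort$condition_attenuation
  ratio <- if (group == "left") cohort$group_effect_ratio else 1
  ep$truth <- list(z = z, subject_scale = subject_scale,
                   depth_early = min(base_depth * ratio * depth_scale, 0.95),
                   depth_late = min(base_depth * depth_scale, 0.95))
  ep
}

#' Simulate a full cohort
#'
#' Deterministic given `cohort$seed`; per-subject seeds are derived from the
#' master seed. Left-handed subjects are generated first.
#'
#' @param template an [erp_template_spec()].
#' @param cohort a [cohort_spec()].
#' @param layout optional `sensor_layout`.
#' @return list with `subjects` (list of `epoch_set`), `groups` (character),
#'   and `truth` (data frame of per-subject ground truth).
#' @export
simulate_cohort <- function(template, cohort, layout = NULL) {
  layout <- layout %||% load_montage()
  groups <- c(rep("left", cohort$n_left), rep("right", cohort$n_right))
  ids <- sprintf("%s%02d", ifelse(groups == "left", "L", "R"),
                 c(seq_len(cohort$n_left), seq_len(cohort$n_right)))
  subjects <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ep <- simulate_subject_epochs(template, cohort, ids[i], groups[i],
                                  seed = subject_seed(cohort$seed, i),
                                  layout = layout)
    subjects[[i]] <- ep
    truth[[i]] <- data.frame(subject = ids[i], group = groups[i],
                             z = ep$truth$z,
                             subject_scale = ep$truth$subject_scale,
                             depth_early = ep$truth$depth_early,
                             depth_late = ep$truth$depth_late,
                             stringsAsFactors = FALSE)
  }
  list(subjects = subjects, groups = groups, truth = do.call(rbind, truth))
}

subject_seed <- function(master, i) (as.integer(master) + 7919L * i) %% 2147483647L

#' Inject labelled artifacts into an epoch set
#'
#' Blink artifacts are 150-microvolt Gaussian deflections (SD 40 ms) added to
#' Fp1, Fp2 and VEOG at a random latency, sized to exceed the 35-microvolt
#' windowed-SD rejection criterion. Range artifacts are 130-microvolt
#' half-sine excursions over 100 ms in one random scalp channel, exceeding
#' the 100-microvolt peak-to-peak criterion.
#'
#' @param epochs an `epoch_set`.
#' @param artifact_rates list with per-epoch probabilities `blink`, `range`.
#' @param seed RNG seed.
#' @return list with `epochs` (modified) and `labels` (data frame: epoch,
#'   type) giving the ground-truth artifact epochs.
#' @export
inject_artifacts <- function(epochs, artifact_rates = list(blink = 0.05,
                                                           range = 0.02),
                             seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  set.seed(seed)
  n <- dim(epochs$data)[1]
  n_t <- dim(epochs$data)[3]
  blink <- runif(n) < (artifact_rates$blink %||% 0)
  range_a <- !blink & runif(n) < (artifact_rates$range %||% 0)
  labels <- list()
  blink_ch <- intersect(c("Fp1", "Fp2", "VEOG"), epochs$channels)
  scalp <- setdiff(epochs$channels, c("HEOG", "VEOG"))
  for (e in which(blink)) {
    t0 <- sample.int(n_t - 200L, 1) + 100L
    pulse <- 150 * exp(-((seq_len(n_t) - t0)^2) / (2 * 40^2))
    for (ch in blink_ch) {
      epochs$data[e, match(ch, epochs$channels), ] <-
        epochs$data[e, match(ch, epochs$channels), ] + pulse
    }
    labels[[length(labels) + 1L]] <- data.frame(epoch = e, type = "blink")
  }
  for (e in which(range_a)) {
    ch <- sample(scalp, 1)
    t0 <- sample.int(n_t - 120L, 1)
    idx <- t0:(t0 + 99L)
    epochs$data[e, match(ch, epochs$channels), idx] <-
      epochs$data[e, match(ch, epochs$channels), idx] +
      130 * sin(pi * seq(0, 1, length.out = 100))
    labels[[length(labels) + 1L]] <- data.frame(epoch = e, type = "range")
  }
  labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(epoch = integer(), type = character())
  labels <- labels[order(labels$epoch), , drop = FALSE]
  rownames(labels) <- NULL
  list(epochs = epochs, labels = labels)
}

#' Behaviour specification
#'
#' Defaults follow the study's behavioural summary structure: vection is
#' nearly always reported for coherent motion and rarely for incoherent
#' motion; coherent vection starts earlier, lasts longer and feels stronger.
#'
#' @param presence_prob named per-condition probabilities of a vection-present
#'   trial.
#' @param latency_median,latency_sdlog named per-condition log-normal onset
#'   latency parameters (s).
#' @param duration_median,duration_sdlog per-condition log-normal total
#'   vection duration parameters (s).
#' @param strength_center per-condition centre of the 0-10 strength scale for
#'   vection-present trials.
#' @param strength_subject_sd SD of the subject-level strength shift mapped
#'   from the latent susceptibility (default 2.2).
#' @param strength_trial_sd per-trial strength jitter SD (default 0.8).
#' @param strength_brain_coupling Gaussian-copula correlation between the
#'   subject's attenuation-depth latent and the subject strength latent
#'   (default 0.8).
#' @return a `behavior_spec`.
#' @export
behavior_spec <- function(presence_prob = c(coherent = 0.95, incoherent = 0.08),
                          latency_median = c(coherent = 6, incoherent = 12),
                          latency_sdlog = c(coherent = 0.45, incoherent = 0.35),
                          duration_median = c(coherent = 13, incoherent = 4.5),
                          duration_sdlog = c(coherent = 0.35, incoherent = 0.5),
                          strength_center = c(coherent = 5.25, incoherent = 1.5),
                          strength_subject_sd = 2.2, strength_trial_sd = 0.8,
                          strength_brain_coupling = 0.8) {
  stopifnot(all(presence_prob >= 0 & presence_prob <= 1),
            abs(strength_brain_coupling) <= 1)
  structure(list(presence_prob = presence_prob,
                 latency_median = latency_median,
                 latency_sdlog = latency_sdlog,
                 duration_median = duration_median,
                 duration_sdlog = duration_sdlog,
                 strength_center = strength_center,
                 strength_subject_sd = strength_subject_sd,
                 strength_trial_sd = strength_trial_sd,
                 strength_brain_coupling = strength_brain_coupling),
            class = "behavior_spec")
}

#' Simulate one subject's behavioural trials for one condition
#'
#' The subject strength latent is a Gaussian copula on the attenuation
#' latent: `s = c * z + sqrt(1 - c^2) * eps`, where `z = qnorm(u_att)` and
#' `c` is `strength_brain_coupling`, so stronger planted ERP attenuation
#' goes with higher reported vection strength at rank level.
#'
#' @param bspec a [behavior_spec()].
#' @param n_trials number of trials.
#' @param condition `"coherent"` or `"incoherent"`.
#' @param subject_attenuation the subject's attenuation-depth quantile in
#'   (0, 1) (rank of the planted attenuation depth within the cohort).
#' @param seed RNG seed.
#' @param directions optional per-trial direction vector (default alternating
#'   cw/ccw).
#' @param motion_duration,post_duration stimulus timing (s), defaults 20 + 10.
#' @param jitter_range pre-motion stationary jitter bounds (s).
#' @return behaviour data frame (see [behavior_table]).
#' @export
simulate_behavior <- function(bspec, n_trials, condition,
                              subject_attenuation = 0.5, seed = 1L,
                              directions = NULL, motion_duration = 20,
                              post_duration = 10, jitter_range = c(3, 5)) {
  stopifnot(condition %in% conditions_ok,
            subject_attenuation > 0, subject_attenuation < 1)
  set.seed(seed)
  cc <- bspec$strength_brain_coupling
  z <- qnorm(subject_attenuation)
  s_latent <- cc * z + sqrt(1 - cc^2) * rnorm(1)
  s_center <- bspec$strength_center[[condition]] +
    bspec$strength_subject_sd * s_latent

  dirs <- directions %||% rep(directions_ok, length.out = n_trials)
  onset <- runif(n_trials, jitter_range[1], jitter_range[2])
  present <- runif(n_trials) < bspec$presence_prob[[condition]]
  lat <- pmin(rlnorm(n_trials, log(bspec$latency_median[[condition]]),
                     bspec$latency_sdlog[[condition]]),
              motion_duration - 0.5)
  dur <- rlnorm(n_trials, log(bspec$duration_median[[condition]]),
                bspec$duration_sdlog[[condition]])
  trial_end <- motion_duration + post_duration  # relative to motion onset
  dur <- pmin(dur, trial_end - lat)
  strength <- pmax(0, pmin(10, round(s_center +
                                       rnorm(n_trials, sd = bspec$strength_trial_sd))))
  strength[!present] <- 0L

  v_on <- ifelse(present, onset + lat, NA)
  v_off <- ifelse(present, onset + lat + dur, NA)
  data.frame(
    trial = seq_len(n_trials),
    condition = condition,
    direction = dirs,
    strength = as.integer(strength),
    motion_onset = onset,
    motion_offset = onset + motion_duration,
    vection_onsets = ifelse(present, vapply(v_on, join_times, character(1)), ""),
    vection_offsets = ifelse(present, vapply(v_off, join_times, character(1)), ""),
    stringsAsFactors = FALSE)
}
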