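#' Behavioural vection metrics and group comparisons
#'
#' Per-trial button-press streams become presence / onset latency / duration
#' / strength measures; per-participant condition summaries are medians over
#' qualifying trials; left- versus right-hander contrasts use the Wilcoxon
#' rank-sum test (normal approximation with tie correction and continuity
#' correction) with Bonferroni adjustment and effect sizes r = Z/sqrt(N).
#'
#' @name behavior_metrics
NULL

#' Derive per-trial vection metrics from button events
#'
#' Presence is one or more vection intervals; onset latency is the first
#' interval onset minus motion onset; duration is the total vection time
#' (sum of interval lengths; intervals still open at motion offset run into
#' the 10 s post-motion period and an interval still open at trial end is
#' closed there). Offsets preceding any onset are dropped with a warning.
#'
#' @param tab behaviour data frame (see [behavior_table]).
#' @param post_duration post-motion stationary period, s (default 10).
#' @return data frame: trial, condition, direction, strength, presence,
#'   onset_latency (s, NA if absent), duration (s, 0 if absent).
#' @export
derive_trial_metrics <- function(tab, post_duration = 10) {
  tab <- validate_behavior_table(tab)
  out <- tab[, c("trial", "condition", "direction", "strength")]
  out$presence <- FALSE
  out$onset_latency <- NA_real_
  out$duration <- 0
  for (i in seq_len(nrow(tab))) {
    onsets <- split_times(tab$vection_onsets[i])
    offsets <- split_times(tab$vection_offsets[i])
    trial_end <- tab$motion_offset[i] + post_duration
    iv <- pair_intervals(onsets, offsets, trial_end)
    if (nrow(iv)) {
      out$presence[i] <- TRUE
      out$onset_latency[i] <- iv$onset[1] - tab$motion_onset[i]
      out$duration[i] <- sum(iv$offset - iv$onset)
    }
  }
  out
}

# Pair time-ordered onset/offset presses into intervals; an unmatched final
# onset closes at trial end, offsets before any onset are dropped.
pair_intervals <- function(onsets, offsets, trial_end) {
  ev <- data.frame(time = c(onsets, offsets),
                   type = rep(c("on", "off"), c(length(onsets), length(offsets))))
  ev <- ev[order(ev$time), , drop = FALSE]
  open_t <- NA_real_
  iv <- list()
  for (j in seq_len(nrow(ev))) {
    if (ev$type[j] == "on") {
      if (is.na(open_t)) open_t <- ev$time[j]
    } else {
      if (is.na(open_t)) {
        warning("vection offset before any onset; event dropped")
      } else {
        iv[[length(iv) + 1L]] <- c(open_t, ev$time[j])
        open_t <- NA_real_
      }
    }
  }
  if (!is.na(open_t)) iv[[length(iv) + 1L]] <- c(open_t, trial_end)
  if (!length(iv)) {
    return(data.frame(onset = numeric(), offset = numeric()))
  }
  m <- do.call(rbind, iv)
  data.frame(onset = m[, 1], offset = m[, 2])
}

#' Per-participant condition summary
#'
#' Presence count over all condition trials; latency and duration medians
#' over vection-present trials only (missing if none); strength median over
#' all condition trials (vection-absent trials contribute their 0 rating).
#'
#' @param metrics per-trial metrics from [derive_trial_metrics()].
#' @param condition `"coherent"` or `"incoherent"`.
#' @return one-row data frame: condition, n_trials, presence_count,
#'   onset_latency, duration, strength.
#' @export
summarize_participant <- function(metrics, condition) {
  m <- metrics[metrics$condition == condition, , drop = FALSE]
  stopifnot(nrow(m) >= 1)
  pres <- m[m$presence, , drop = FALSE]
  data.frame(condition = condition, n_trials = nrow(m),
             presence_count = sum(m$presence),
             onset_latency = if (nrow(pres)) median(pres$onset_latency) else NA_real_,
             duration = if (nrow(pres)) median(pres$duration) else NA_real_,
             strength = median(m$strength),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum group comparison
#'
#' Z is the normal approximation with average ranks for ties, tie-corrected
#' variance and a 0.5 continuity correction, signed as left minus right
#' (positive Z: left-handers larger). Effect size r = Z / sqrt(N) with N
#' the total number of observations. Missing values are dropped.
#'
#' @param left,right numeric vectors of per-participant values.
#' @param m Bonferroni family size (default 8: 4 measures x 2 conditions).
#' @return one-row data frame: n_left, n_right, Z, p, p_adjusted, r,
#'   median_left, iqr_left, median_right, iqr_right.
#' @export
compare_groups <- function(left, right, m = 8) {
  left <- left[!is.na(left)]
  right <- right[!is.na(right)]
  stopifnot(length(left) >= 2, length(right) >= 2, m >= 1)
  n1 <- length(left); n2 <- length(right); n <- n1 + n2
  rk <- rank(c(left, right))
  R1 <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    cc <- sign(R1 - mu) * 0.5  # continuity correction toward zero
    num <- R1 - mu - cc
    if (sign(num) != sign(R1 - mu) && (R1 - mu) != 0) num <- 0
    z <- num / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  data.frame(n_left = n1, n_right = n2, Z = z, p = p,
             p_adjusted = min(1, m * p), r = z / sqrt(n),
             median_left = median(left), iqr_left = IQR(left),
             median_right = median(right), iqr_right = IQR(right))
}

#' Exact two-sided rank-sum p value by enumeration
#'
#' Brute-force enumeration of all group assignments; usable as an oracle for
#' small samples (total n limited to 16).
#'
#' @param left,right numeric vectors.
#' @return exact two-sided p value for the rank-sum statistic.
#' @export
ranksum_exact_p <- function(left, right) {
  n1 <- length(left); n <- n1 + length(right)
  stopifnot(n <= 16)
  pooled <- c(left, right)
  rk <- rank(pooled)
  obs <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combs <- combn(n, n1)
  stat <- colSums(matrix(rk[combs], nrow = n1))
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-12)
}

behavior_measures <- c("presence_count", "onset_latency", "duration", "strength")

#' Group comparison table across measures and conditions
#'
#' Runs [compare_groups()] for every behavioural measure in both conditions
#' (the Bonferroni family), reproducing the structure of the study's
#' behavioural summary table: per-group medians with interquartile ranges,
#' Z, p, adjusted p and r.
#'
#' @param summaries data frame of per-participant summaries with columns
#'   `subject`, `group`, `condition`, and the four measures.
#' @param m Bonferroni family size (default 8).
#' @return data frame with one row per measure x condition.
#' @export
behavior_group_table <- function(summaries, m = 8) {
  rows <- list()
  for (cond in conditions_ok) {
    s <- summaries[summaries$condition == cond, , drop = FALSE]
    for (meas in behavior_measures) {
      cmpr <- compare_groups(s[[meas]][s$group == "left"],
                             s[[meas]][s$group == "right"], m = m)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(measure = meas, condition = cond,
                         stringsAsFactors = FALSE), cmpr)
    }
  }
  do.call(rbind, rows)
}
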