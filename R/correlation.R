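#' Brain-behaviour correlations
#'
#' After the condition contrast identifies its largest significant cluster,
#' each subject's coherent-condition window mean amplitudes are averaged
#' over the cluster electrodes and correlated (Spearman's rho, groups
#' pooled) with the four behavioural vection measures, with Bonferroni
#' correction over the four tests per window.
#'
#' @name correlation_analysis
NULL

#' Cluster mean amplitude per subject
#'
#' @param amplitudes subjects x electrodes matrix (coherent-condition window
#'   mean amplitudes, columns named by electrode).
#' @param cluster_electrodes character vector of cluster member electrodes.
#' @return named numeric vector, one unweighted cluster mean per subject.
#' @export
extract_cluster_amplitude <- function(amplitudes, cluster_electrodes) {
  if (!length(cluster_electrodes)) {
    stop_vection("empty cluster: no correlation is defined", "vection_empty_set_error")
  }
  missing_el <- setdiff(cluster_electrodes, colnames(amplitudes))
  if (length(missing_el)) {
    stop_vection(paste("cluster electrodes absent:",
                       paste(missing_el, collapse = ", ")),
                 "vection_validation_error")
  }
  rowMeans(amplitudes[, cluster_electrodes, drop = FALSE])
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks; the two-sided p value
#' uses the t approximation with n - 2 degrees of freedom (`method =
#' "approx"`), or exact enumeration of all rank permutations (`method =
#' "exact"`, n limited to 8). Zero rank variance in either variable yields
#' `rho = NA` with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 4); ties allowed.
#' @param method `"approx"` (default) or `"exact"`.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y, method = c("approx", "exact")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 4)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("zero rank variance: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  if (method == "exact") {
    if (n > 8) stop_vection("exact Spearman limited to n <= 8",
                            "vection_validation_error")
    perms <- permutations_all(n)
    rhos <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (is.finite(tval)) 2 * pt(-abs(tval), n - 2) else 0
  }
  list(rho = rho, p = p, n = n)
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_all(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(sub + (sub >= i), i))
  }
  out
}

#' Bonferroni adjustment
#'
#' @param p p value(s).
#' @param m family size (>= 1).
#' @return `min(1, m * p)`, vectorised.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Correlate cluster amplitude with the behavioural measures
#'
#' @param cluster_amplitude named per-subject cluster mean amplitudes
#'   (microvolts), groups pooled.
#' @param behavior data frame with `subject` plus the four measures
#'   (coherent-condition per-participant summaries).
#' @param window label recorded in the output (`"early"` or `"late"`).
#' @param m Bonferroni family size (default 4, the four measures).
#' @return data frame: measure, window, rho, p, p_adjusted, n.
#' @export
correlate_brain_behavior <- function(cluster_amplitude, behavior,
                                     window = "early", m = 4) {
  stopifnot(all(behavior_measures %in% names(behavior)))
  amp <- cluster_amplitude[match(behavior$subject, names(cluster_amplitude))]
  rows <- lapply(behavior_measures, function(meas) {
    res <- spearman_correlation(amp, behavior[[meas]])
    data.frame(measure = meas, window = window, rho = res$rho, p = res$p,
               p_adjusted = bonferroni_adjust(res$p, m), n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
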