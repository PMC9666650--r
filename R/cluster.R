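#' Spatial cluster-based permutation tests
#'
#' Family-wise-error-controlled tests on per-electrode window mean
#' amplitudes. Electrode-level t statistics are thresholded at p < 0.01;
#' suprathreshold electrodes are grouped into spatially connected,
#' same-sign clusters; each cluster's mass is the sum of its member t
#' values; and the observed cluster with the largest absolute mass is
#' compared against the 99th percentile of the permutation null
#' distribution of the maximum absolute mass (1000 permutations by
#' default). The paired design (condition contrast) permutes by random
#' per-subject sign flips of the condition differences; the independent
#' design (handedness contrast) permutes group labels over the per-subject
#' condition differences.
#'
#' @name cluster_permutation
NULL

#' Electrode-level t tests
#'
#' Paired design: one-sample t on per-subject differences (`a` is a
#' subjects x electrodes matrix of differences, or supply both `a` and `b`
#' as matched condition matrices). Independent design: two-sample
#' pooled-variance t comparing the rows of `a` (group 1) with the rows of
#' `b` (group 2). Electrodes with zero variance get t = 0, p = 1 with a
#' warning.
#'
#' @param a,b subjects x electrodes matrices (see above).
#' @param design `"paired"` or `"independent"`.
#' @return data frame with `electrode`, `t`, `p`, plus the design and group
#'   sizes as attributes.
#' @export
electrode_level_test <- function(a, b = NULL,
                                 design = c("paired", "independent")) {
  design <- match.arg(design)
  if (design == "paired") {
    d <- if (is.null(b)) a else a - b
    n <- nrow(d)
    stopifnot(n >= 2)
    m <- colMeans(d)
    v <- colSums(sweep(d, 2, m)^2) / (n - 1)
    se <- sqrt(v / n)
    df <- n - 1
    tval <- ifelse(se > 0, m / se, 0)
  } else {
    stopifnot(!is.null(b), nrow(a) >= 2, nrow(b) >= 2)
    n1 <- nrow(a); n2 <- nrow(b)
    m1 <- colMeans(a); m2 <- colMeans(b)
    vp <- (colSums(sweep(a, 2, m1)^2) + colSums(sweep(b, 2, m2)^2)) /
      (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    tval <- ifelse(se > 0, (m1 - m2) / se, 0)
  }
  if (any(se == 0)) warning("zero-variance electrode(s): t set to 0, p to 1")
  p <- ifelse(se > 0, 2 * pt(-abs(tval), df), 1)
  out <- data.frame(electrode = colnames(a) %||% paste0("e", seq_along(tval)),
                    t = tval, p = p, stringsAsFactors = FALSE)
  attr(out, "design") <- design
  attr(out, "df") <- df
  out
}

#' Form same-sign spatially connected clusters
#'
#' Electrodes with p below `alpha` are partitioned into maximal connected
#' components of the adjacency graph restricted to electrodes whose t
#' values share a sign. Cluster mass is the exact sum of member t values.
#' Clusters are returned sorted by decreasing absolute mass, ties broken by
#' larger electrode count and then by lexicographically smallest member
#' set, so results are deterministic.
#'
#' @param stats data frame from [electrode_level_test()].
#' @param adjacency logical electrode-by-electrode matrix (same order).
#' @param alpha electrode-level threshold (default 0.01).
#' @return list of clusters, each `list(members, sign, mass)`; empty list
#'   if no electrode is suprathreshold.
#' @export
form_clusters <- function(stats, adjacency, alpha = 0.01) {
  stopifnot(nrow(stats) == nrow(adjacency))
  supra <- which(stats$p < alpha & stats$t != 0)
  if (!length(supra)) return(list())
  sgn <- sign(stats$t)
  clusters <- list()
  unvisited <- supra
  while (length(unvisited)) {
    seed_el <- unvisited[1]
    comp <- seed_el
    frontier <- seed_el
    while (length(frontier)) {
      nbr <- unique(unlist(lapply(frontier, function(v) which(adjacency[v, ]))))
      nbr <- setdiff(intersect(nbr, unvisited),
                     comp)
      nbr <- nbr[sgn[nbr] == sgn[seed_el]]
      comp <- c(comp, nbr)
      frontier <- nbr
    }
    unvisited <- setdiff(unvisited, comp)
    comp <- sort(comp)
    clusters[[length(clusters) + 1L]] <-
      list(members = stats$electrode[comp], sign = sgn[seed_el],
           mass = sum(stats$t[comp]))
  }
  ord <- order(-vapply(clusters, function(cl) abs(cl$mass), numeric(1)),
               -vapply(clusters, function(cl) length(cl$members), integer(1)),
               vapply(clusters, function(cl) paste(cl$members, collapse = ","),
                      character(1)))
  clusters[ord]
}

# Max |mass| over clusters formed from vectors of t and p (internal fast
# path used inside the permutation loop).
max_cluster_mass <- function(tval, p, adjacency, alpha) {
  supra <- which(p < alpha & tval != 0)
  if (!length(supra)) return(0)
  sgn <- sign(tval)
  best <- 0
  unvisited <- supra
  while (length(unvisited)) {
    seed_el <- unvisited[1]
    comp <- seed_el
    frontier <- seed_el
    while (length(frontier)) {
      nbr <- unique(unlist(lapply(frontier, function(v) which(adjacency[v, ]))))
      nbr <- intersect(nbr, unvisited)
      nbr <- setdiff(nbr, comp)
      nbr <- nbr[sgn[nbr] == sgn[seed_el]]
      comp <- c(comp, nbr)
      frontier <- nbr
    }
    unvisited <- setdiff(unvisited, comp)
    best <- max(best, abs(sum(tval[comp])))
  }
  best
}

#' Cluster-based permutation test
#'
#' @param diffs subjects x electrodes matrix of per-subject condition
#'   differences (coherent minus incoherent window mean amplitudes).
#' @param groups for the independent design, a character/factor vector of
#'   group labels aligned with the rows of `diffs`; ignored for paired.
#' @param adjacency logical electrode adjacency matrix, columns aligned
#'   with `diffs`.
#' @param design `"paired"` (sign-flip null) or `"independent"` (label
#'   permutation null).
#' @param n_perm number of permutations (default 1000; minimum 100), or
#'   `"exact"` to enumerate the full permutation space (paired designs with
#'   up to 20 subjects).
#' @param alpha_cluster electrode-level threshold for cluster formation
#'   (default 0.01).
#' @param seed RNG seed (always recorded in the result).
#' @param method `"auto"` (default: Monte-Carlo sampling, falling back to
#'   exact enumeration with a warning when fewer than 100 distinct
#'   permutations exist), `"montecarlo"` (always sample, with replacement if
#'   need be) or `"exact"`.
#' @param critical_quantile quantile of the null max-|mass| distribution
#'   used as the significance cutoff (default 0.99, the 99th percentile).
#' @return a `cluster_test_result`: observed clusters, `largest_cluster`,
#'   `max_mass`, `null_max_mass`, `critical_value` (99th percentile of the
#'   null), `p_value` with the +1/+1 correction, `significant`
#'   (`max_mass > critical_value`), and bookkeeping fields.
#' @export
permutation_test <- function(diffs, groups = NULL, adjacency,
                             design = c("paired", "independent"),
                             n_perm = 1000, alpha_cluster = 0.01, seed = 1L,
                             method = c("auto", "montecarlo", "exact"),
                             critical_quantile = 0.99) {
  design <- match.arg(design)
  method <- match.arg(method)
  exact <- identical(n_perm, "exact") || method == "exact"
  if (!exact && n_perm < 100) {
    stop_vection("n_perm must be at least 100 (or \"exact\")",
                 "vection_validation_error")
  }
  n <- nrow(diffs)
  E <- ncol(diffs)
  stopifnot(ncol(adjacency) == E)

  if (design == "paired") {
    obs_stats <- electrode_level_test(diffs, design = "paired")
    df <- n - 1
    if (!exact && 2^n < 100 && method == "auto") {
      warning("fewer than 100 distinct sign-flip patterns; using exact enumeration")
      exact <- TRUE
    }
    if (exact) {
      if (n > 20) stop_vection("exact enumeration limited to 20 subjects",
                               "vection_validation_error")
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      set.seed(seed)
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
    }
    ss <- colSums(diffs^2)  # invariant under sign flips
    M <- (signs %*% diffs) / n
    Vc <- sweep(-(n * M^2), 2, ss, `+`) / (n - 1)
    Tmat <- M / sqrt(pmax(Vc, 0) / n)
    Tmat[!is.finite(Tmat)] <- 0
  } else {
    stopifnot(!is.null(groups), length(groups) == n)
    g <- as.character(groups)
    lev <- unique(g)
    stopifnot(length(lev) == 2)
    i1 <- which(g == lev[1])
    obs_stats <- electrode_level_test(diffs[i1, , drop = FALSE],
                                      diffs[-i1, , drop = FALSE],
                                      design = "independent")
    df <- n - 2
    n1 <- length(i1); n2 <- n - n1
    if (exact) {
      combs <- combn(n, n1)
      if (ncol(combs) > 1e4) stop_vection("exact enumeration too large",
                                          "vection_validation_error")
      G <- matrix(0, ncol(combs), n)
      G[cbind(rep(seq_len(ncol(combs)), each = n1), as.vector(combs))] <- 1
    } else {
      set.seed(seed)
      G <- t(vapply(seq_len(n_perm), function(i) {
        z <- numeric(n); z[sample.int(n, n1)] <- 1; z
      }, numeric(n)))
    }
    ssq_tot <- colSums(diffs^2)
    S1 <- G %*% diffs
    Q1 <- G %*% diffs^2
    m1 <- S1 / n1
    m2 <- sweep(-S1, 2, colSums(diffs), `+`) / n2
    ss1 <- Q1 - n1 * m1^2
    ss2 <- sweep(-Q1, 2, ssq_tot, `+`) - n2 * m2^2
    vp <- (ss1 + ss2) / (n1 + n2 - 2)
    Tmat <- (m1 - m2) / sqrt(pmax(vp, 0) * (1 / n1 + 1 / n2))
    Tmat[!is.finite(Tmat)] <- 0
  }

  tcrit <- qt(1 - alpha_cluster / 2, df)
  obs_clusters <- form_clusters(obs_stats, adjacency, alpha_cluster)
  obs_max <- if (length(obs_clusters)) abs(obs_clusters[[1]]$mass) else 0

  null_max <- numeric(nrow(Tmat))
  for (i in seq_len(nrow(Tmat))) {
    tv <- Tmat[i, ]
    if (any(abs(tv) > tcrit)) {
      pv <- 2 * pt(-abs(tv), df)
      null_max[i] <- max_cluster_mass(tv, pv, adjacency, alpha_cluster)
    }
  }

  n_eff <- length(null_max)
  critical <- as.numeric(quantile(null_max, critical_quantile))
  p_value <- (1 + sum(null_max >= obs_max)) / (n_eff + 1)
  structure(list(clusters = obs_clusters,
                 largest_cluster = if (length(obs_clusters)) obs_clusters[[1]] else NULL,
                 max_mass = obs_max,
                 electrode_stats = obs_stats,
                 null_max_mass = null_max,
                 critical_value = critical,
                 p_value = p_value,
                 significant = obs_max > critical,
                 design = design, n_permutations = n_eff,
                 alpha_cluster = alpha_cluster, exact = exact, seed = seed),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %s design, %d permutations%s\n",
              x$design, x$n_permutations, if (x$exact) " (exact)" else ""))
  cat(sprintf("  clusters: %d; max |mass| = %.3f; critical (99th pct) = %.3f; p = %.4f%s\n",
              length(x$clusters), x$max_mass, x$critical_value, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
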