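#' Pipeline configuration
#'
#' Bundles every stage's parameters with explicit seeds so that a run is
#' fully reproducible from its config alone.
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"brainvision"` (ingest
#'   recorded files listed in `subjects`).
#' @param template an [erp_template_spec()].
#' @param cohort a [cohort_spec()] (synthetic mode).
#' @param behavior a [behavior_spec()].
#' @param criteria a [rejection_criteria()].
#' @param windows named list of analysis windows, ms (default
#'   [erp_windows]).
#' @param n_perm permutations for the cluster tests (>= 100; default 1000).
#' @param alpha_cluster electrode-level cluster-forming threshold (0.01).
#' @param m_behavior,m_correlation Bonferroni family sizes (8 and 4).
#' @param min_trials per-condition inclusion minimum (30).
#' @param seed master seed; all stage seeds derive from it.
#' @param subjects brainvision mode: data frame with `subject`, `group`,
#'   `header_path`, `behavior_path`.
#' @param code_map brainvision mode: marker code map for
#'   [read_brainvision()].
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "brainvision"),
                            template = erp_template_spec(),
                            cohort = cohort_spec(),
                            behavior = behavior_spec(),
                            criteria = rejection_criteria(),
                            windows = erp_windows,
                            n_perm = 1000, alpha_cluster = 0.01,
                            m_behavior = 8, m_correlation = 4,
                            min_trials = 30, seed = 1L,
                            subjects = NULL, code_map = NULL) {
  mode <- match.arg(mode)
  if (!identical(n_perm, "exact") && n_perm < 100) {
    stop_vection("n_perm below the minimum of 100", "vection_validation_error")
  }
  structure(list(mode = mode, template = template, cohort = cohort,
                 behavior = behavior, criteria = criteria, windows = windows,
                 n_perm = n_perm, alpha_cluster = alpha_cluster,
                 m_behavior = m_behavior, m_correlation = m_correlation,
                 min_trials = min_trials, seed = as.integer(seed),
                 subjects = subjects, code_map = code_map),
            class = "pipeline_config")
}

# Preprocess one subject's epochs and extract per-condition window mean
# amplitudes (scalp channels only). Returns NULL rows for excluded subjects.
process_subject_epochs <- function(ep, config) {
  ep <- baseline_correct(ep)
  rej <- reject_artifacts(ep, config$criteria)
  kept <- rej$kept
  counts <- table(factor(kept$labels$condition, levels = conditions_ok))
  included <- check_participant_inclusion(counts[["coherent"]],
                                          counts[["incoherent"]],
                                          config$min_trials)
  amps <- NULL
  if (included) {
    amps <- lapply(config$windows, function(win) {
      sapply(conditions_ok, function(cond) {
        wv <- average_condition(kept, cond)
        a <- window_mean_amplitude(wv, win)
        a[!is_eog_channel(names(a))]
      })
    })
  }
  list(included = included, counts = as.integer(counts),
       rejection_log = rej$log, amplitudes = amps)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: simulates the cohort subject by subject (epochs plus
#' behaviour), applies baseline correction, sliding-window artifact
#' rejection and the participant inclusion rule, computes per-subject window
#' mean amplitudes, runs the cluster-based permutation tests (condition
#' contrast pooled and per group; handedness contrast on the condition
#' differences) in both windows, compares behavioural measures between
#' groups, and correlates the pooled condition-contrast cluster amplitude
#' with behaviour. All stages are deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, result tables
#'   (CSV/JSON) and a reproducibility manifest are written.
#' @param layout optional `sensor_layout`; default the shipped montage with
#'   Delaunay adjacency.
#' @return list with elements `inclusion`, `amplitudes`, `cluster_tests`,
#'   `behavior_summaries`, `behavior_comparisons`, `correlations`, `truth`,
#'   `config`.
#' @export
run_all <- function(config, out_dir = NULL, layout = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  layout <- layout %||% build_adjacency(load_montage())
  if (is.null(layout$adjacency)) layout <- build_adjacency(layout)

  if (config$mode == "synthetic") {
    cohort <- config$cohort
    groups_all <- c(rep("left", cohort$n_left), rep("right", cohort$n_right))
    ids <- sprintf("%s%02d", ifelse(groups_all == "left", "L", "R"),
                   c(seq_len(cohort$n_left), seq_len(cohort$n_right)))
    per_subj <- vector("list", length(ids))
    truth <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      ep <- simulate_subject_epochs(config$template, cohort, ids[i],
                                    groups_all[i],
                                    seed = subject_seed(cohort$seed, i),
                                    layout = layout)
      truth[[i]] <- data.frame(subject = ids[i], group = groups_all[i],
                               z = ep$truth$z,
                               depth_early = ep$truth$depth_early,
                               depth_late = ep$truth$depth_late)
      inj <- inject_artifacts(ep, cohort$artifact_rates,
                              seed = subject_seed(cohort$seed + 1000L, i))
      per_subj[[i]] <- process_subject_epochs(inj$epochs, config)
      per_subj[[i]]$subject <- ids[i]
      per_subj[[i]]$group <- groups_all[i]
    }
    truth <- do.call(rbind, truth)
  } else {
    stopifnot(is.data.frame(config$subjects))
    ids <- config$subjects$subject
    groups_all <- config$subjects$group
    per_subj <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      rec <- read_brainvision(config$subjects$header_path[i], config$code_map)
      rec <- apply_filters(rec)
      rec <- rereference_common_average(rec)
      ep <- epoch_recording(rec)
      ep$labels$subject <- ids[i]
      ep$labels$group <- groups_all[i]
      per_subj[[i]] <- process_subject_epochs(ep, config)
      per_subj[[i]]$subject <- ids[i]
      per_subj[[i]]$group <- groups_all[i]
    }
    truth <- NULL
  }

  inclusion <- data.frame(
    subject = ids, group = groups_all,
    n_coherent = vapply(per_subj, function(s) s$counts[1], integer(1)),
    n_incoherent = vapply(per_subj, function(s) s$counts[2], integer(1)),
    included = vapply(per_subj, function(s) s$included, logical(1)),
    stringsAsFactors = FALSE)
  rejection_log <- do.call(rbind, lapply(per_subj, function(s) {
    cbind(subject = s$subject, s$rejection_log)
  }))

  inc <- which(inclusion$included)
  if (length(inc) < 4) {
    stop_vection("fewer than 4 included participants; cannot run statistics",
                 "vection_empty_set_error")
  }
  scalp <- layout$channels
  amplitudes <- lapply(names(config$windows), function(wn) {
    coh <- t(vapply(per_subj[inc], function(s) s$amplitudes[[wn]][, "coherent"],
                    numeric(length(scalp))))
    incoh <- t(vapply(per_subj[inc],
                      function(s) s$amplitudes[[wn]][, "incoherent"],
                      numeric(length(scalp))))
    colnames(coh) <- colnames(incoh) <- scalp
    rownames(coh) <- rownames(incoh) <- ids[inc]
    list(coherent = coh, incoherent = incoh)
  })
  names(amplitudes) <- names(config$windows)
  groups_inc <- factor(groups_all[inc], levels = c("left", "right"))

  cluster_tests <- list()
  for (wn in names(config$windows)) {
    d <- amplitudes[[wn]]$coherent - amplitudes[[wn]]$incoherent
    cluster_tests[[paste0("condition_pooled_", wn)]] <-
      permutation_test(d, adjacency = layout$adjacency, design = "paired",
                       n_perm = config$n_perm,
                       alpha_cluster = config$alpha_cluster,
                       seed = subject_seed(config$seed + 11L, match(wn, names(config$windows))))
    for (g in levels(groups_inc)) {
      cluster_tests[[paste0("condition_", g, "_", wn)]] <-
        permutation_test(d[groups_inc == g, , drop = FALSE],
                         adjacency = layout$adjacency, design = "paired",
                         n_perm = config$n_perm,
                         alpha_cluster = config$alpha_cluster,
                         seed = subject_seed(config$seed + 13L, match(wn, names(config$windows))))
    }
    cluster_tests[[paste0("handedness_", wn)]] <-
      permutation_test(d, groups = groups_inc, adjacency = layout$adjacency,
                       design = "independent", n_perm = config$n_perm,
                       alpha_cluster = config$alpha_cluster,
                       seed = subject_seed(config$seed + 17L, match(wn, names(config$windows))))
  }

  # Behaviour: no participants are excluded from the behavioural analyses.
  if (config$mode == "synthetic") {
    # Couple behaviour to the latent susceptibility (which drives each
    # subject's attenuation depth within group), not to the group-scaled
    # depth itself: handedness must not leak into the behavioural measures.
    u_att <- rank(truth$z) / (nrow(truth) + 1)
    schedule_seed <- subject_seed(config$seed + 23L, 1L)
    summaries <- list()
    for (i in seq_along(ids)) {
      sched <- make_session_schedule(seed = subject_seed(schedule_seed, i))
      trials <- do.call(rbind, lapply(conditions_ok, function(cond) {
        n_tr <- sum(sched$condition == cond)
        simulate_behavior(config$behavior, n_tr, cond,
                          subject_attenuation = u_att[i],
                          seed = subject_seed(config$seed + 29L,
                                              i * 2L + match(cond, conditions_ok)),
                          directions = sched$direction[sched$condition == cond])
      }))
      mets <- derive_trial_metrics(trials)
      for (cond in conditions_ok) {
        s <- summarize_participant(mets, cond)
        s$subject <- ids[i]; s$group <- groups_all[i]
        summaries[[length(summaries) + 1L]] <- s
      }
    }
    behavior_summaries <- do.call(rbind, summaries)
  } else {
    summaries <- list()
    for (i in seq_along(ids)) {
      trials <- read_behavior_table(config$subjects$behavior_path[i])
      mets <- derive_trial_metrics(trials)
      for (cond in conditions_ok) {
        s <- summarize_participant(mets, cond)
        s$subject <- ids[i]; s$group <- groups_all[i]
        summaries[[length(summaries) + 1L]] <- s
      }
    }
    behavior_summaries <- do.call(rbind, summaries)
  }
  behavior_comparisons <- behavior_group_table(behavior_summaries,
                                               m = config$m_behavior)

  # Brain-behaviour correlations: coherent-condition amplitude averaged over
  # the pooled condition-contrast cluster of the matching window, against
  # the coherent-condition behavioural summaries, groups pooled.
  correlations <- list()
  beh_coh <- behavior_summaries[behavior_summaries$condition == "coherent", ]
  for (wn in names(config$windows)) {
    ct <- cluster_tests[[paste0("condition_pooled_", wn)]]
    if (!is.null(ct$largest_cluster) && ct$significant) {
      amp <- extract_cluster_amplitude(amplitudes[[wn]]$coherent,
                                       ct$largest_cluster$members)
      beh <- beh_coh[beh_coh$subject %in% names(amp), ]
      correlations[[wn]] <- correlate_brain_behavior(amp, beh, window = wn,
                                                     m = config$m_correlation)
    }
  }
  correlations <- if (length(correlations)) do.call(rbind, correlations) else NULL

  results <- list(inclusion = inclusion, rejection_log = rejection_log,
                  amplitudes = amplitudes, cluster_tests = cluster_tests,
                  behavior_summaries = behavior_summaries,
                  behavior_comparisons = behavior_comparisons,
                  correlations = correlations, truth = truth,
                  layout = layout, config = config)
  if (!is.null(out_dir)) write_pipeline_results(results, out_dir)
  results
}

cluster_result_record <- function(name, ct) {
  list(contrast = name,
       n_permutations = ct$n_permutations,
       seed = ct$seed,
       max_mass = ct$max_mass,
       critical_value = ct$critical_value,
       p_value = ct$p_value,
       significant = ct$significant,
       clusters = lapply(ct$clusters, function(cl) {
         list(members = as.list(cl$members), sign = cl$sign, mass = cl$mass)
       }))
}

#' Write pipeline result tables
#'
#' Writes the rejection log, inclusion report, per-window amplitude
#' matrices, cluster test records (JSON), behavioural summaries and
#' comparisons, correlation table and a reproducibility manifest.
#'
#' @param results value of [run_all()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_results_table(results$inclusion, p("inclusion.csv"))
  write_results_table(results$rejection_log, p("rejection_log.csv"))
  for (wn in names(results$amplitudes)) {
    for (cond in conditions_ok) {
      m <- results$amplitudes[[wn]][[cond]]
      write_results_table(cbind(subject = rownames(m), as.data.frame(m)),
                          p(sprintf("amplitudes_%s_%s.csv", wn, cond)))
    }
  }
  recs <- lapply(names(results$cluster_tests), function(nm) {
    cluster_result_record(nm, results$cluster_tests[[nm]])
  })
  jsonlite::write_json(recs, p("cluster_tests.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_results_table(results$behavior_summaries, p("behavior_summaries.csv"))
  write_results_table(results$behavior_comparisons, p("behavior_comparisons.csv"))
  if (!is.null(results$correlations)) {
    write_results_table(results$correlations, p("correlations.csv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("vection")),
    mode = results$config$mode,
    seed = results$config$seed,
    n_perm = results$config$n_perm,
    alpha_cluster = results$config$alpha_cluster,
    windows = results$config$windows,
    min_trials = results$config$min_trials,
    adjacency = results$layout$adjacency_method,
    n_subjects = nrow(results$inclusion),
    n_included = sum(results$inclusion$included))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
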