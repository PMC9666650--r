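#' Behavioural trial tables
#'
#' Per-trial behaviour is stored as a data frame with one row per trial:
#' `trial` (integer id), `condition` (`coherent`/`incoherent`), `direction`
#' (`cw`/`ccw`), `motion_onset` and `motion_offset` (seconds in trial time),
#' `strength` (integer 0-10 verbal rating), and `vection_onsets` /
#' `vection_offsets` (semicolon-separated second values, empty when no
#' vection was reported). Button-press intervals are ordered and
#' non-overlapping; an onset still open at trial end is closed at trial end
#' by [derive_trial_metrics()].
#'
#' @name behavior_table
NULL

conditions_ok <- c("coherent", "incoherent")
directions_ok <- c("cw", "ccw")

#' Read a behavioural trial table
#'
#' @param path CSV file with a header row naming at least `trial`,
#'   `condition`, `direction`, `strength`, `motion_onset`, `motion_offset`,
#'   `vection_onsets`, `vection_offsets`.
#' @return validated behaviour data frame (see [behavior_table]).
#' @export
read_behavior_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(vection_onsets = "character",
                                 vection_offsets = "character"))
  validate_behavior_table(tab)
}

#' @rdname read_behavior_table
#' @param tab behaviour data frame to validate.
#' @export
validate_behavior_table <- function(tab) {
  need <- c("trial", "condition", "direction", "strength",
            "motion_onset", "motion_offset", "vection_onsets", "vection_offsets")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_vection(paste("behaviour table missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 "vection_validation_error")
  }
  bad_cond <- setdiff(unique(tab$condition), conditions_ok)
  if (length(bad_cond)) {
    stop_vection(paste("unknown condition:", paste(bad_cond, collapse = ", ")),
                 "vection_validation_error")
  }
  bad_dir <- setdiff(unique(tab$direction), directions_ok)
  if (length(bad_dir)) {
    stop_vection(paste("unknown direction:", paste(bad_dir, collapse = ", ")),
                 "vection_validation_error")
  }
  s <- tab$strength
  if (any(is.na(s)) || any(s != round(s)) || any(s < 0 | s > 10)) {
    stop_vection("strength must be an integer on the 0-10 scale",
                 "vection_validation_error")
  }
  tab$strength <- as.integer(tab$strength)
  tab$vection_onsets[is.na(tab$vection_onsets)] <- ""
  tab$vection_offsets[is.na(tab$vection_offsets)] <- ""
  tab[need]
}

#' Write a behavioural or results table as CSV
#'
#' @param tab data frame.
#' @param path output path (UTF-8, comma-separated, header row).
#' @export
write_results_table <- function(tab, path) {
  ok <- tryCatch({
    write.csv(tab, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_vection(paste("cannot write", path), "vection_io_error")
  invisible(path)
}

#' Split/join semicolon-separated second lists
#' @noRd
split_times <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

join_times <- function(x) paste(format(x, trim = TRUE, digits = 10), collapse = ";")
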