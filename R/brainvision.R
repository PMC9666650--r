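#' Continuous EEG recordings
#'
#' A `recording` holds continuous multichannel EEG as a channels-by-samples
#' numeric matrix in microvolts, together with the sampling rate, ordered
#' channel labels (10-10 names plus bipolar EOG channels), the current
#' reference, and a typed event table.
#'
#' Events are stored in a data frame with columns `sample_index` (0-based
#' offset into the recording), `kind` (one of `motion_onset`, `motion_offset`,
#' `vection_onset_cw`, `vection_onset_ccw`, `vection_offset_cw`,
#' `vection_offset_ccw`, `trial_start`), `condition` (`coherent`,
#' `incoherent`, `none`) and `direction` (`cw`, `ccw`, `none`).
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param srate sampling rate in Hz (> 0); 1000 Hz in the study design.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param reference reference label, or `"common_average"`.
#' @param events event data frame as described above (may have zero rows).
#' @return an object of class `recording`.
#' @export
new_recording <- function(data, srate, channel_labels,
                          reference = "FCz", events = empty_events()) {
  data <- as.matrix(data)
  if (length(channel_labels) != nrow(data)) {
    stop_vection("channel_labels must match rows of data", "vection_validation_error")
  }
  if (anyDuplicated(channel_labels)) {
    stop_vection("duplicate channel labels", "vection_validation_error")
  }
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0) {
    stop_vection("srate must be a positive scalar", "vection_validation_error")
  }
  events <- validate_events(events, ncol(data))
  rownames(data) <- channel_labels
  structure(list(data = data, srate = srate, channel_labels = channel_labels,
                 reference = reference, events = events,
                 provenance = list()),
            class = "recording")
}

event_kinds <- c("motion_onset", "motion_offset", "vection_onset_cw",
                 "vection_onset_ccw", "vection_offset_cw",
                 "vection_offset_ccw", "trial_start")

#' @rdname new_recording
#' @export
empty_events <- function() {
  data.frame(sample_index = integer(), kind = character(),
             condition = character(), direction = character(),
             stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples) {
  stopifnot(is.data.frame(events))
  need <- c("sample_index", "kind", "condition", "direction")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols)) {
    stop_vection(paste("event table missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 "vection_validation_error")
  }
  if (nrow(events)) {
    if (any(events$sample_index < 0 | events$sample_index >= n_samples)) {
      stop_vection("event sample_index outside recording", "vection_validation_error")
    }
    bad <- setdiff(unique(events$kind), event_kinds)
    if (length(bad)) {
      stop_vection(paste("unknown event kind:", paste(bad, collapse = ", ")),
                   "vection_validation_error")
    }
  }
  events[need]
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz, ref %s, %d events\n",
              nrow(x$data), ncol(x$data), x$srate, x$reference, nrow(x$events)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# BrainVision triad (.vhdr header / .vmrk markers / .eeg binary data)
#
# Only the multiplexed orientation is supported, with IEEE_FLOAT_32 or
# INT_16 binary encodings; vectorized files are rejected explicitly. Marker
# descriptions are mapped to typed events via a user-supplied code map,
# because trigger codes are site-specific.
# ---------------------------------------------------------------------------

#' Read a BrainVision recording
#'
#' @param header_path path to the `.vhdr` header file.
#' @param code_map named list mapping marker description strings (e.g.
#'   `"S 10"`) to lists with elements `kind`, and optionally `condition` and
#'   `direction`. Markers with descriptions not present in the map are
#'   ignored.
#' @return a [new_recording()] object with data scaled to microvolts.
#' @export
read_brainvision <- function(header_path, code_map = list()) {
  if (!file.exists(header_path)) {
    stop_vection(paste("header file not found:", header_path), "vection_io_error")
  }
  hdr <- parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]] %||% list()
  bi <- hdr[["Binary Infos"]] %||% list()
  if (toupper(ci$DataFormat %||% "BINARY") != "BINARY") {
    stop_vection("only BINARY DataFormat is supported", "vection_unsupported_dialect")
  }
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (orientation != "MULTIPLEXED") {
    stop_vection(paste("unsupported data orientation:", orientation),
                 "vection_unsupported_dialect")
  }
  binfmt <- toupper(bi$BinaryFormat %||% "IEEE_FLOAT_32")
  if (!binfmt %in% c("IEEE_FLOAT_32", "INT_16")) {
    stop_vection(paste("unsupported binary format:", binfmt),
                 "vection_unsupported_dialect")
  }
  n_chan <- as.integer(ci$NumberOfChannels)
  srate <- 1e6 / as.numeric(ci$SamplingInterval)  # header stores microseconds
  chinfo <- parse_channel_infos(hdr[["Channel Infos"]], n_chan)
  if (anyDuplicated(chinfo$label)) {
    stop_vection("duplicate channel labels in header", "vection_validation_error")
  }

  dir <- dirname(header_path)
  data_path <- file.path(dir, ci$DataFile)
  marker_path <- if (!is.null(ci$MarkerFile)) file.path(dir, ci$MarkerFile) else NULL
  if (!file.exists(data_path)) {
    stop_vection(paste("data file not found:", data_path), "vection_io_error")
  }

  sz <- file.info(data_path)$size
  if (binfmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(data_path, "numeric", n = sz / 4, size = 4)
  } else {
    raw_vals <- readBin(data_path, "integer", n = sz / 2, size = 2, signed = TRUE)
  }
  n_samp <- length(raw_vals) %/% n_chan
  mat <- matrix(raw_vals[seq_len(n_chan * n_samp)], nrow = n_chan)  # multiplexed
  mat <- mat * chinfo$resolution  # per-channel resolution -> microvolts

  events <- empty_events()
  if (!is.null(marker_path)) {
    if (!file.exists(marker_path)) {
      stop_vection(paste("marker file not found:", marker_path), "vection_io_error")
    }
    events <- parse_vmrk(readLines(marker_path, warn = FALSE), code_map, n_samp)
  }
  new_recording(mat, srate, chinfo$label, reference = ci$Reference %||% "FCz",
                events = events)
}

#' Write a BrainVision triad
#'
#' Writes `base_path.vhdr`, `base_path.vmrk` and `base_path.eeg` in the
#' multiplexed IEEE float32 dialect.
#'
#' @param rec a [new_recording()] object.
#' @param base_path path without extension.
#' @param code_map optional named list (as in [read_brainvision()]); when
#'   given, marker descriptions are chosen so that reading with the same map
#'   restores the typed events. Without a map, descriptions encode the event
#'   kind/condition/direction directly.
#' @return `base_path`, invisibly.
#' @export
write_brainvision <- function(rec, base_path, code_map = NULL) {
  stopifnot(inherits(rec, "recording"))
  vhdr <- paste0(base_path, ".vhdr")
  vmrk <- paste0(base_path, ".vmrk")
  eeg <- paste0(base_path, ".eeg")
  base <- basename(base_path)
  n_chan <- nrow(rec$data)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_chan),
    paste0("Reference=", rec$reference),
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_chan), rec$channel_labels)
  )
  ok <- tryCatch({
    writeLines(hdr, vhdr, useBytes = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_vection(paste("cannot write", vhdr), "vection_io_error")

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  ev <- rec$events
  if (nrow(ev)) {
    desc <- event_descriptions(ev, code_map)
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(ev)) + 1L, desc, ev$sample_index + 1L))
  }
  writeLines(mk, vmrk, useBytes = FALSE)

  writeBin(as.numeric(rec$data), eeg, size = 4)  # column-major == multiplexed
  invisible(base_path)
}

# Default self-describing marker descriptions: "kind|condition|direction".
event_descriptions <- function(ev, code_map) {
  if (is.null(code_map)) {
    return(paste(ev$kind, ev$condition, ev$direction, sep = "|"))
  }
  keys <- vapply(seq_len(nrow(ev)), function(i) {
    hit <- Filter(function(m) {
      identical(m$kind, ev$kind[i]) &&
        identical(m$condition %||% "none", ev$condition[i]) &&
        identical(m$direction %||% "none", ev$direction[i])
    }, code_map)
    if (!length(hit)) {
      stop_vection(sprintf("no code map entry for event %s/%s/%s",
                           ev$kind[i], ev$condition[i], ev$direction[i]),
                   "vection_validation_error")
    }
    names(hit)[1]
  }, character(1))
  keys
}

parse_vmrk <- function(lines, code_map, n_samples) {
  mk <- grep("^Mk[0-9]+=", lines, value = TRUE)
  out <- empty_events()
  for (ln in mk) {
    body <- sub("^Mk[0-9]+=", "", ln)
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    if (length(parts) < 3 || parts[1] == "New Segment") next
    desc <- parts[2]
    pos <- as.integer(parts[3]) - 1L  # file positions are 1-based
    typed <- NULL
    if (length(code_map) && desc %in% names(code_map)) {
      m <- code_map[[desc]]
      typed <- list(kind = m$kind, condition = m$condition %||% "none",
                    direction = m$direction %||% "none")
    } else if (grepl("|", desc, fixed = TRUE)) {
      f <- strsplit(desc, "|", fixed = TRUE)[[1]]
      if (length(f) == 3 && f[1] %in% event_kinds) {
        typed <- list(kind = f[1], condition = f[2], direction = f[3])
      }
    }
    if (is.null(typed)) next
    out <- rbind(out, data.frame(sample_index = pos, kind = typed$kind,
                                 condition = typed$condition,
                                 direction = typed$direction,
                                 stringsAsFactors = FALSE))
  }
  validate_events(out, n_samples)
}

parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(section)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[section]][[key]] <- val
    }
  }
  out
}

parse_channel_infos <- function(section, n_chan) {
  if (is.null(section)) {
    stop_vection("header lacks [Channel Infos]", "vection_validation_error")
  }
  label <- character(n_chan)
  resolution <- numeric(n_chan)
  for (i in seq_len(n_chan)) {
    entry <- section[[paste0("Ch", i)]]
    if (is.null(entry)) {
      stop_vection(paste0("header missing Ch", i), "vection_validation_error")
    }
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    label[i] <- parts[1]
    res <- if (length(parts) >= 3) parts[3] else ""
    resolution[i] <- if (nzchar(res)) as.numeric(res) else 1
  }
  list(label = label, resolution = resolution)
}
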