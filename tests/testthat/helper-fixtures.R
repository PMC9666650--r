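# Shared fixtures, built in code at test time.

the_layout <- build_adjacency(load_montage())

# A tiny noise-free recording with motion-onset events, for IO and
# preprocessing tests.
make_tiny_recording <- function(n_chan = 4, n_samp = 3000, srate = 1000,
                                labels = c("Fp1", "Fz", "Cz", "VEOG"),
                                events = NULL) {
  data <- matrix(seq_len(n_chan * n_samp) %% 17 - 8, n_chan, n_samp)
  events <- events %||% data.frame(
    sample_index = c(500L, 1500L),
    kind = "motion_onset",
    condition = c("coherent", "incoherent"),
    direction = c("cw", "ccw"),
    stringsAsFactors = FALSE)
  new_recording(data, srate, labels, events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Epoch set with deterministic content: value v in every sample of every
# channel, or a custom filler function of (epoch, channel) returning a
# length-n_time vector.
make_flat_epochs <- function(n_epochs = 4, channels = c("Fp1", "Fz", "Cz", "VEOG"),
                             n_time = 600, value = 0, fill = NULL,
                             conditions = rep(c("coherent", "incoherent"),
                                              length.out = n_epochs)) {
  data <- array(value, c(n_epochs, length(channels), n_time))
  if (!is.null(fill)) {
    for (e in seq_len(n_epochs)) for (c in seq_along(channels)) {
      data[e, c, ] <- fill(e, c)
    }
  }
  new_epoch_set(data, times = seq(-200, by = 1, length.out = n_time),
                channels = channels,
                labels = data.frame(epoch = seq_len(n_epochs),
                                    condition = conditions,
                                    direction = rep(c("cw", "ccw"),
                                                    length.out = n_epochs),
                                    subject = "s01", group = "right",
                                    stringsAsFactors = FALSE))
}

# Window whose sample standard deviation is exactly 35 (alternating +/-a
# with a^2 = 35^2 * (n-1)/n lands on 35.0 in double precision for n = 200).
boundary_sd_window <- function() {
  a <- sqrt(1218.875)
  rep(c(a, -a), 100)
}
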