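#' Rotating dot-field stimulus kinematics
#'
#' The visual stimulus is a field of randomly placed dots rotating in the
#' roll plane about the line of sight. In the coherent (vection-consistent)
#' condition every dot follows a rigid circular trajectory at the global
#' angular velocity. In the incoherent (vection-inconsistent) condition each
#' dot additionally receives an independent sinusoidal offset in X and Y,
#' with phase, amplitude and frequency randomised per dot per axis, so that
#' individual dots move erratically while the field keeps the same mean
#' global angular velocity.
#'
#' @param n_dots number of dots (default 1000).
#' @param omega signed global angular velocity in deg/s; positive is
#'   counter-clockwise (default 30, the study velocity).
#' @param duration motion duration in seconds (default 20).
#' @param frame_rate frames per second (default 60).
#' @param perturb_amp_range per-axis sinusoid amplitude bounds, degrees of
#'   visual field (default `c(0.5, 3)`).
#' @param perturb_freq_range sinusoid frequency bounds in Hz (default
#'   `c(0.2, 1)`).
#' @param field_radius field radius in degrees; the field subtends twice
#'   this angle (default 50, i.e. a 100 degree field).
#' @param seed RNG seed.
#' @return a `dot_field_spec` list.
#' @export
dot_field_spec <- function(n_dots = 1000, omega = 30, duration = 20,
                           frame_rate = 60, perturb_amp_range = c(0.5, 3),
                           perturb_freq_range = c(0.2, 1),
                           field_radius = 50, seed = 1L) {
  stopifnot(n_dots >= 1, frame_rate > 0, duration > 0, field_radius > 0)
  if (max(perturb_amp_range) > field_radius) {
    stop_vection("perturbation amplitude exceeds field radius",
                 "vection_validation_error")
  }
  structure(list(n_dots = n_dots, omega = omega, duration = duration,
                 frame_rate = frame_rate,
                 perturb_amp_range = perturb_amp_range,
                 perturb_freq_range = perturb_freq_range,
                 field_radius = field_radius, seed = as.integer(seed)),
            class = "dot_field_spec")
}

frame_times <- function(spec) {
  seq(0, spec$duration, by = 1 / spec$frame_rate)
}

# Initial placement: uniform over the disc by area (radius ~ sqrt(u)),
# avoiding the central clustering a uniform radius draw would give.
initial_positions <- function(spec) {
  set.seed(spec$seed)
  r <- spec$field_radius * sqrt(runif(spec$n_dots))
  th <- runif(spec$n_dots, 0, 2 * pi)
  list(r = r, theta = th)
}

#' Generate a coherent (rigid-rotation) dot trajectory
#'
#' @param spec a [dot_field_spec()].
#' @return a `dot_trajectory`: list with `positions` (array dots x frames x 2,
#'   degrees, origin at fixation), `times`, `spec`, and `per_dot_params`
#'   (NULL for coherent fields).
#' @export
generate_coherent <- function(spec) {
  tt <- frame_times(spec)
  init <- initial_positions(spec)
  ang <- outer(init$theta, tt * spec$omega * pi / 180, `+`)
  pos <- array(NA_real_, c(spec$n_dots, length(tt), 2))
  pos[, , 1] <- init$r * cos(ang)
  pos[, , 2] <- init$r * sin(ang)
  structure(list(positions = pos, times = tt, spec = spec,
                 per_dot_params = NULL, coherent = TRUE),
            class = "dot_trajectory")
}

#' Generate an incoherent (per-dot perturbed) dot trajectory
#'
#' Rigid rotation plus an independent sinusoidal offset per dot per axis;
#' phase uniform on `[0, 2*pi)`, amplitude and frequency uniform over the
#' spec ranges, all drawn separately for each dot.
#'
#' @param spec a [dot_field_spec()].
#' @return a `dot_trajectory` with `per_dot_params` (data frame: amp_x,
#'   freq_x, phase_x, amp_y, freq_y, phase_y).
#' @export
generate_incoherent <- function(spec) {
  base <- generate_coherent(spec)  # consumes spec$seed for placement
  set.seed(spec$seed + 1L)         # independent stream for perturbations
  n <- spec$n_dots
  par <- data.frame(
    amp_x = runif(n, spec$perturb_amp_range[1], spec$perturb_amp_range[2]),
    freq_x = runif(n, spec$perturb_freq_range[1], spec$perturb_freq_range[2]),
    phase_x = runif(n, 0, 2 * pi),
    amp_y = runif(n, spec$perturb_amp_range[1], spec$perturb_amp_range[2]),
    freq_y = runif(n, spec$perturb_freq_range[1], spec$perturb_freq_range[2]),
    phase_y = runif(n, 0, 2 * pi))
  tt <- base$times
  wx <- 2 * pi * outer(par$freq_x, tt)
  wy <- 2 * pi * outer(par$freq_y, tt)
  offs_x <- par$amp_x * sin(sweep(wx, 1, par$phase_x, `+`))
  offs_y <- par$amp_y * sin(sweep(wy, 1, par$phase_y, `+`))
  pos <- base$positions
  pos[, , 1] <- pos[, , 1] + offs_x
  pos[, , 2] <- pos[, , 2] + offs_y
  structure(list(positions = pos, times = tt, spec = spec,
                 per_dot_params = par, coherent = FALSE),
            class = "dot_trajectory")
}

#' Across-dot mean angular speed of a trajectory
#'
#' For each dot the polar angle about the fixation origin is unwrapped over
#' frames in `[t0, t1]`; the dot's net angular displacement divided by the
#' window length is its mean angular velocity. Dots whose radius falls below
#' `r_floor` at any frame (angle undefined near the origin) are excluded,
#' with the exclusion count reported as an attribute.
#'
#' @param traj a `dot_trajectory`.
#' @param t0,t1 window bounds in seconds within the trajectory duration.
#' @param r_floor numeric radius floor in degrees (default 1e-6).
#' @return across-dot mean angular speed in deg/s (signed as `omega`), with
#'   attribute `n_excluded`.
#' @export
mean_global_angular_speed <- function(traj, t0 = 0, t1 = NULL,
                                      r_floor = 1e-6) {
  t1 <- t1 %||% max(traj$times)
  if (t1 <= t0) stop_vection("t1 must exceed t0", "vection_validation_error")
  sel <- traj$times >= t0 - 1e-12 & traj$times <= t1 + 1e-12
  x <- traj$positions[, sel, 1, drop = FALSE][, , 1]
  y <- traj$positions[, sel, 2, drop = FALSE][, , 1]
  r <- sqrt(x^2 + y^2)
  ok <- apply(r >= r_floor, 1, all)
  ang <- atan2(y, x)
  d <- ang[, -1, drop = FALSE] - ang[, -ncol(ang), drop = FALSE]
  d <- (d + pi) %% (2 * pi) - pi  # unwrap frame-to-frame jumps
  net <- rowSums(d)
  speed <- net[ok] * 180 / pi / (t1 - t0)
  structure(mean(speed), n_excluded = sum(!ok))
}

#' Build a single-trial stimulus timeline
#'
#' Each trial presents the dots stationary for a jittered 3-5 s period, then
#' rotating for 20 s, then stationary again for 10 s.
#'
#' @param spec a [dot_field_spec()] (provides the motion duration).
#' @param jitter_range bounds of the uniform pre-motion jitter in seconds
#'   (default `c(3, 5)`).
#' @param post_duration post-motion stationary period, seconds (default 10).
#' @param seed RNG seed for the jitter draw.
#' @return data frame with columns `segment` and `duration` (s).
#' @export
build_trial_timeline <- function(spec = dot_field_spec(),
                                 jitter_range = c(3, 5), post_duration = 10,
                                 seed = 1L) {
  set.seed(seed)
  pre <- runif(1, jitter_range[1], jitter_range[2])
  data.frame(segment = c("stationary_pre", "rotating", "stationary_post"),
             duration = c(pre, spec$duration, post_duration),
             stringsAsFactors = FALSE)
}

#' Generate a session trial schedule
#'
#' 100 trials per participant: 50 coherent and 50 incoherent, 25 clockwise
#' and 25 counter-clockwise within each condition, presented in random order
#' in blocks of 10.
#'
#' @param n_per_cell trials per condition x direction cell (default 25).
#' @param block_size trials per block (default 10).
#' @param seed RNG seed for the order shuffle.
#' @return data frame with `trial`, `block`, `condition`, `direction`.
#' @export
make_session_schedule <- function(n_per_cell = 25, block_size = 10, seed = 1L) {
  cells <- expand.grid(condition = conditions_ok, direction = directions_ok,
                       stringsAsFactors = FALSE)
  tab <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  set.seed(seed)
  tab <- tab[sample.int(nrow(tab)), ]
  tab$trial <- seq_len(nrow(tab))
  tab$block <- (tab$trial - 1L) %/% block_size + 1L
  rownames(tab) <- NULL
  tab[, c("trial", "block", "condition", "direction")]
}
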