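#' Synthetic trial configuration
#'
#' Builds the configuration object for the synthetic two-channel signal
#' generator.  A trial holds an EOG channel (uV) and a strain channel
#' (relative resistance change dR/R0) sampled on a common uniform grid.
#' Horizontal saccades appear as a single signed raised-cosine spike of
#' 500--600 uV on the EOG channel (left gaze positive, right gaze negative);
#' vertical gaze appears as a slow rise--hold--fall plateau on the strain
#' channel (downward gaze stretches the forehead epidermis, so its resistance
#' increases; upward gaze compresses it).  Straight trials carry no event.
#' Additive disturbances emulate 50 Hz powerline pickup, white measurement
#' noise and slow baseline drift; `electrode_mode = "rigid"` emulates the
#' poorer skin contact of a conventional rigid electrode by scaling the
#' powerline and white-noise amplitudes.
#'
#' @param sampling_rate sampling rate in Hz (default 250; must exceed 100 so
#'   the 50 Hz interferer is representable).
#' @param trial_duration trial length in seconds (default 4).
#' @param eog_spike_amplitude_range two-element range of saccade spike peak
#'   amplitudes in uV (default `c(500, 600)`).
#' @param eog_spike_duration_range two-element range of spike durations in
#'   seconds (default `c(0.15, 0.35)`).
#' @param strain_rel_magnitude nominal plateau magnitude of the strain event
#'   as dR/R0 (default 0.02; each trial jitters it by +/-10%).
#' @param strain_rise_time plateau rise/fall time in seconds (default 0.6).
#' @param strain_hold_range two-element range of plateau hold times in
#'   seconds (default `c(1.0, 1.6)`).
#' @param powerline_amplitude 50 Hz interference amplitude in uV (default 20).
#' @param white_noise_sd white noise standard deviation in uV (default 15).
#' @param drift_amplitude baseline drift amplitude in uV (default 30; the
#'   drift period is twice the trial length, so at most half a cycle per
#'   trial).
#' @param electrode_mode `"flexible"` (hydrogel sensor) or `"rigid"`
#'   (conventional electrode; multiplies powerline and white-noise
#'   amplitudes by `rigid_noise_factor`).
#' @param rigid_noise_factor noise multiplier for rigid mode (default 2).
#' @param strain_noise_scale conversion from the uV noise amplitudes to the
#'   strain channel's dR/R0 units (default 4e-5 per uV, i.e. the strain
#'   channel receives scaled-down copies of the same disturbances).
#' @param down_is_stretch logical; if `TRUE` (default) downward gaze
#'   stretches the epidermis (dR > 0) and upward gaze compresses it
#'   (dR < 0).  Set `FALSE` to flip the convention.
#' @param seed optional default seed recorded in the config.
#' @return an object of class `trace_config`.
#' @examples
#' cfg <- trace_config()
#' tr <- generate_trial("left", cfg, seed = 7)
#' range(tr$eog)
#' @seealso [generate_trial()], [add_noise()], [generate_dataset()]
#' @export
trace_config <- function(sampling_rate = 250,
                         trial_duration = 4.0,
                         eog_spike_amplitude_range = c(500, 600),
                         eog_spike_duration_range = c(0.15, 0.35),
                         strain_rel_magnitude = 0.02,
                         strain_rise_time = 0.6,
                         strain_hold_range = c(1.0, 1.6),
                         powerline_amplitude = 20,
                         white_noise_sd = 15,
                         drift_amplitude = 30,
                         electrode_mode = c("flexible", "rigid"),
                         rigid_noise_factor = 2.0,
                         strain_noise_scale = 4e-5,
                         down_is_stretch = TRUE,
                         seed = NULL) {
  electrode_mode <- match.arg(electrode_mode)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (sampling_rate <= 100) {
    stop("sampling_rate must exceed 100 Hz (2 x the 50 Hz powerline)",
         call. = FALSE)
  }
  check_scalar(trial_duration, "trial_duration", positive = TRUE)
  stopifnot(length(eog_spike_amplitude_range) == 2,
            length(eog_spike_duration_range) == 2,
            length(strain_hold_range) == 2)
  if (diff(eog_spike_amplitude_range) < 0 ||
      diff(eog_spike_duration_range) < 0 ||
      diff(strain_hold_range) < 0) {
    stop("range parameters must satisfy low <= high", call. = FALSE)
  }
  check_scalar(strain_rel_magnitude, "strain_rel_magnitude", positive = TRUE)
  check_scalar(strain_rise_time, "strain_rise_time", positive = TRUE)
  check_scalar(powerline_amplitude, "powerline_amplitude", nonneg = TRUE)
  check_scalar(white_noise_sd, "white_noise_sd", nonneg = TRUE)
  check_scalar(drift_amplitude, "drift_amplitude", nonneg = TRUE)
  check_scalar(rigid_noise_factor, "rigid_noise_factor", positive = TRUE)
  check_scalar(strain_noise_scale, "strain_noise_scale", nonneg = TRUE)
  structure(
    list(
      sampling_rate = sampling_rate,
      trial_duration = trial_duration,
      eog_spike_amplitude_range = eog_spike_amplitude_range,
      eog_spike_duration_range = eog_spike_duration_range,
      strain_rel_magnitude = strain_rel_magnitude,
      strain_rise_time = strain_rise_time,
      strain_hold_range = strain_hold_range,
      powerline_amplitude = powerline_amplitude,
      white_noise_sd = white_noise_sd,
      drift_amplitude = drift_amplitude,
      electrode_mode = electrode_mode,
      rigid_noise_factor = rigid_noise_factor,
      strain_noise_scale = strain_noise_scale,
      down_is_stretch = down_is_stretch,
      seed = seed
    ),
    class = "trace_config"
  )
}

#' @export
print.trace_config <- function(x, ...) {
  cat("<trace_config> ", x$sampling_rate, " Hz x ", x$trial_duration, " s, ",
      "EOG spikes [", x$eog_spike_amplitude_range[1], ", ",
      x$eog_spike_amplitude_range[2], "] uV, strain ",
      x$strain_rel_magnitude, " dR/R0, mode=", x$electrode_mode, "\n",
      sep = "")
  invisible(x)
}

# Raised-cosine (Hann) unipolar pulse on grid t.
raised_cosine_pulse <- function(t, onset, duration, amplitude) {
  u <- (t - onset) / duration
  y <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  y[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  y
}

# Rise--hold--fall plateau with half-cosine ramps.
plateau_pulse <- function(t, onset, rise, hold, amplitude) {
  u <- t - onset
  y <- numeric(length(t))
  up <- u >= 0 & u < rise
  y[up] <- 0.5 * (1 - cos(pi * u[up] / rise))
  y[u >= rise & u < rise + hold] <- 1
  v <- u - rise - hold
  dn <- v >= 0 & v <= rise
  y[dn] <- 0.5 * (1 + cos(pi * v[dn] / rise))
  amplitude * y
}

empty_events <- function() {
  data.frame(channel = character(), onset = numeric(),
             duration = numeric(), amplitude = numeric(),
             stringsAsFactors = FALSE)
}

#' Generate one labeled synthetic trial
#'
#' Produces a `labeled_trace` for the requested gaze state: the clean
#' event waveform for that state plus the configured noise (via
#' [add_noise()]).  Deterministic for a fixed seed.
#'
#' @param state one of `"straight"`, `"up"`, `"down"`, `"left"`, `"right"`.
#' @param config a [trace_config()].
#' @param seed integer seed for this trial.
#' @return a `labeled_trace`: list with `t` (s), `eog` (uV), `strain_rel`
#'   (dR/R0), `state`, `events` (data frame with columns `channel`, `onset`,
#'   `duration`, `amplitude`) and `sampling_rate`.
#' @examples
#' tr <- generate_trial("left", trace_config(white_noise_sd = 0,
#'   powerline_amplitude = 0, drift_amplitude = 0), seed = 7)
#' max(tr$eog)  # inside [500, 600]
#' @export
generate_trial <- function(state, config = trace_config(), seed = 1L) {
  check_state(state)
  stopifnot(inherits(config, "trace_config"))
  n <- round(config$sampling_rate * config$trial_duration)
  t <- (seq_len(n) - 1) / config$sampling_rate
  eog <- numeric(n)
  strain <- numeric(n)
  events <- empty_events()

  with_seed(seed, {
    if (state %in% c("left", "right")) {
      amp <- runif(1, config$eog_spike_amplitude_range[1],
                   config$eog_spike_amplitude_range[2])
      if (state == "right") amp <- -amp
      dur <- runif(1, config$eog_spike_duration_range[1],
                   config$eog_spike_duration_range[2])
      margin <- min(0.5, (config$trial_duration - dur) / 4)
      onset <- runif(1, margin, config$trial_duration - dur - margin)
      eog <- raised_cosine_pulse(t, onset, dur, amp)
      events <- data.frame(channel = "eog", onset = onset, duration = dur,
                           amplitude = amp, stringsAsFactors = FALSE)
    } else if (state %in% c("up", "down")) {
      mag <- config$strain_rel_magnitude * runif(1, 0.9, 1.1)
      stretch <- if (config$down_is_stretch) state == "down" else state == "up"
      amp <- if (stretch) mag else -mag
      hold <- runif(1, config$strain_hold_range[1], config$strain_hold_range[2])
      dur <- 2 * config$strain_rise_time + hold
      margin <- min(0.3, (config$trial_duration - dur) / 4)
      if (dur + 2 * margin > config$trial_duration) {
        stop("strain event does not fit in the trial; shorten ",
             "strain_hold_range or strain_rise_time", call. = FALSE)
      }
      onset <- runif(1, margin, config$trial_duration - dur - margin)
      strain <- plateau_pulse(t, onset, config$strain_rise_time, hold, amp)
      events <- data.frame(channel = "strain", onset = onset, duration = dur,
                           amplitude = amp, stringsAsFactors = FALSE)
    }
  })

  trace <- structure(
    list(t = t, eog = eog, strain_rel = strain, state = state,
         events = events, sampling_rate = config$sampling_rate),
    class = "labeled_trace"
  )
  add_noise(trace, config, seed = derive_seed(seed, 1L))
}

#' @export
print.labeled_trace <- function(x, ...) {
  cat("<labeled_trace> state=", x$state, ", ", length(x$t), " samples @ ",
      x$sampling_rate, " Hz, ", nrow(x$events), " event(s)\n", sep = "")
  invisible(x)
}

#' Add acquisition noise to a trace
#'
#' Adds 50 Hz powerline interference (random phase), white Gaussian noise and
#' slow sinusoidal baseline drift (period = twice the trial length) to the
#' EOG channel, and scaled-down copies of the same disturbances to the strain
#' channel.  In `electrode_mode = "rigid"` the powerline and white-noise
#' amplitudes are multiplied by `config$rigid_noise_factor`.
#'
#' @param trace a `labeled_trace`.
#' @param config a [trace_config()]; must match the trace's sampling rate.
#' @param seed integer seed.
#' @return the trace with noise added to both channels.
#' @export
add_noise <- function(trace, config, seed = 1L) {
  stopifnot(inherits(trace, "labeled_trace"), inherits(config, "trace_config"))
  if (abs(trace$sampling_rate - config$sampling_rate) > 1e-9) {
    stop("trace sampling rate does not match config", call. = FALSE)
  }
  if (config$sampling_rate <= 100) {
    stop("sampling rate below Nyquist for the 50 Hz powerline", call. = FALSE)
  }
  fac <- if (config$electrode_mode == "rigid") config$rigid_noise_factor else 1
  t <- trace$t
  n <- length(t)
  with_seed(seed, {
    phase_pl <- runif(1, 0, 2 * pi)
    phase_dr <- runif(1, 0, 2 * pi)
    powerline <- fac * config$powerline_amplitude * sin(2 * pi * 50 * t + phase_pl)
    white <- fac * config$white_noise_sd * rnorm(n)
    period <- 2 * config$trial_duration
    drift <- config$drift_amplitude * sin(2 * pi * t / period + phase_dr)
    noise_uv <- powerline + white + drift
    # strain channel sees the same disturbances through a different coupling
    phase_pl2 <- runif(1, 0, 2 * pi)
    phase_dr2 <- runif(1, 0, 2 * pi)
    noise_rel <- config$strain_noise_scale *
      (fac * config$powerline_amplitude * sin(2 * pi * 50 * t + phase_pl2) +
       fac * config$white_noise_sd * rnorm(n) +
       config$drift_amplitude * sin(2 * pi * t / period + phase_dr2))
  })
  trace$eog <- trace$eog + noise_uv
  trace$strain_rel <- trace$strain_rel + noise_rel
  trace
}

#' Generate a balanced labeled dataset
#'
#' Generates `n_trials` labeled trials with class counts differing by at most
#' one across the five gaze states (600 trials gives 120 per state).
#' Per-trial seeds are derived deterministically from the master seed.
#'
#' @param n_trials number of trials (>= 5).
#' @param config a [trace_config()].
#' @param seed master seed.
#' @return an object of class `gaze_dataset`: list with `trials` (list of
#'   `labeled_trace`) and `manifest` (data frame `trial_id`, `state`, `seed`).
#' @examples
#' ds <- generate_dataset(5, trace_config(), seed = 1)
#' table(ds$manifest$state)
#' @export
generate_dataset <- function(n_trials = 600, config = trace_config(),
                             seed = 1L) {
  check_scalar(n_trials, "n_trials", positive = TRUE)
  if (n_trials < length(GAZE_STATES)) {
    stop("n_trials must be at least the number of classes (",
         length(GAZE_STATES), ")", call. = FALSE)
  }
  states <- rep_len(GAZE_STATES, n_trials)
  seeds <- vapply(seq_len(n_trials), function(i) derive_seed(seed, i + 7L),
                  integer(1))
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trials[[i]] <- generate_trial(states[i], config, seed = seeds[i])
  }
  manifest <- data.frame(
    trial_id = sprintf("trial_%04d", seq_len(n_trials)),
    state = states, seed = seeds, stringsAsFactors = FALSE
  )
  structure(list(trials = trials, manifest = manifest, config = config),
            class = "gaze_dataset")
}

#' @export
print.gaze_dataset <- function(x, ...) {
  cat("<gaze_dataset> ", length(x$trials), " trials: ",
      paste(sprintf("%s=%d", names(table(x$manifest$state)),
                    table(x$manifest$state)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read and write trace files
#'
#' Traces are exchanged as delimited text with one header line and columns
#' `t_s`, `eog_uV`, `strain_rel`.  A dataset directory additionally holds
#' `manifest.csv` with columns `trial_id`, `state`, `seed`, `path`.
#'
#' @param trace a `labeled_trace`.
#' @param path file path.
#' @param state optional state label to attach on read (default `NA`).
#' @return `read_trace()` returns a `labeled_trace` (with empty event table);
#'   `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "labeled_trace"))
  df <- data.frame(t_s = trace$t, eog_uV = trace$eog,
                   strain_rel = trace$strain_rel)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, state = NA_character_) {
  df <- read.csv(path)
  need <- c("t_s", "eog_uV", "strain_rel")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dt <- diff(df$t_s)
  fs <- 1 / median(dt)
  structure(
    list(t = df$t_s, eog = df$eog_uV, strain_rel = df$strain_rel,
         state = state, events = empty_events(), sampling_rate = fs),
    class = "labeled_trace"
  )
}

#' Write a dataset to a directory
#'
#' Writes one trace CSV per trial plus `manifest.csv`.
#'
#' @param dataset a `gaze_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest data frame (with a `path` column), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- dataset$manifest
  man$path <- file.path(dir, paste0(man$trial_id, ".csv"))
  for (i in seq_along(dataset$trials)) {
    write_trace(dataset$trials[[i]], man$path[i])
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(man)
}
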