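#' Full pipeline configuration
#'
#' Bundles the per-stage configurations.  The stages run in fixed order:
#' front end -> Kalman -> wavelet separation -> feature extraction ->
#' classifier; the `stages` flags exist only for ablation experiments and
#' are echoed into benchmark reports.
#'
#' @param trace a [trace_config()].
#' @param frontend a [frontend_config()].
#' @param kalman a [kalman_model()].
#' @param wavelet a [wavelet_config()].
#' @param features a [feature_config()].
#' @param classifier list with `sigma` (`NULL` = median heuristic),
#'   `penalty` and `epsilon`.
#' @param stages named logical vector enabling the conditioning stages.
#' @param dwell_time dwell debounce for streaming command output, seconds
#'   (default 0.5).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(trace = trace_config(),
                            frontend = frontend_config(
                              sampling_rate = trace$sampling_rate),
                            kalman = kalman_model(),
                            wavelet = wavelet_config(),
                            features = feature_config(),
                            classifier = list(sigma = NULL, penalty = 1.0,
                                              epsilon = 0.05),
                            stages = c(frontend = TRUE, kalman = TRUE,
                                       wavelet = TRUE),
                            dwell_time = 0.5) {
  stopifnot(inherits(trace, "trace_config"),
            inherits(frontend, "frontend_config"),
            inherits(kalman, "kalman_model"),
            inherits(wavelet, "wavelet_config"),
            inherits(features, "feature_config"))
  if (abs(trace$sampling_rate - frontend$sampling_rate) > 1e-9) {
    stop("trace and frontend sampling rates differ", call. = FALSE)
  }
  stages <- c(frontend = isTRUE(stages[["frontend"]]),
              kalman = isTRUE(stages[["kalman"]]),
              wavelet = isTRUE(stages[["wavelet"]]))
  structure(
    list(trace = trace, frontend = frontend, kalman = kalman,
         wavelet = wavelet, features = features, classifier = classifier,
         stages = stages, dwell_time = dwell_time),
    class = "pipeline_config"
  )
}

#' Mix the two sensor channels into the measured compound signal
#'
#' The forehead biosensor superimposes the EOG potential and the
#' strain-induced voltage in a single measured waveform; this helper forms
#' that compound in uV: `eog + strain_rel * strain_gain_uv`.
#'
#' @param trace a `labeled_trace`.
#' @param strain_gain_uv conditioning gain in uV per unit dR/R0.
#' @return numeric series in uV.
#' @export
mix_channels <- function(trace, strain_gain_uv = 12500) {
  stopifnot(inherits(trace, "labeled_trace"))
  trace$eog + trace$strain_rel * strain_gain_uv
}

#' Condition a trace and extract its feature vector
#'
#' Runs the signal-conditioning stages on one trial and returns the raw
#' (unnormalized) 8-element feature vector along with the intermediate
#' series.
#'
#' @param trace a `labeled_trace` sampled at the configured rate.
#' @param config a [pipeline_config()].
#' @return list with `features`, `eog_component` (uV), `strain_component`
#'   (dR/R0), `eog_events`, `strain_events`, `conditioned` (uV compound
#'   after filtering).
#' @export
process_trace <- function(trace, config = pipeline_config()) {
  stopifnot(inherits(trace, "labeled_trace"),
            inherits(config, "pipeline_config"))
  fs <- config$trace$sampling_rate
  if (abs(trace$sampling_rate - fs) > 1e-6 * fs) {
    stop("trace sampling rate (", round(trace$sampling_rate, 3),
         " Hz) does not match the configured rate (", fs, " Hz)",
         call. = FALSE)
  }
  x <- mix_channels(trace, config$frontend$strain_gain_uv)
  if (config$stages[["frontend"]]) {
    x <- apply_frontend(x, config$frontend)
  }
  if (config$stages[["kalman"]]) {
    x <- kalman_filter_trace(x, config$kalman)
  }
  if (config$stages[["wavelet"]]) {
    sep <- separate_components(x, config$wavelet, sampling_rate = fs)
  } else {
    sep <- list(strain = x, eog = x, mask = rep(0, length(x)))
  }
  strain_rel <- sep$strain / config$frontend$strain_gain_uv
  ev_eog <- detect_events(sep$eog, trace$t,
                          threshold = config$features$eog_threshold_uv,
                          min_duration = config$features$min_duration)
  ev_strain <- detect_events(strain_rel, trace$t,
                             threshold = config$features$strain_threshold_rel,
                             min_duration = config$features$min_duration)
  feats <- extract_features(ev_eog, ev_strain)
  list(features = feats, eog_component = sep$eog,
       strain_component = strain_rel, eog_events = ev_eog,
       strain_events = ev_strain, conditioned = x)
}

#' Feature table for a whole dataset
#'
#' Applies [process_trace()] to every trial of a dataset.
#'
#' @param dataset a `gaze_dataset`.
#' @param config a [pipeline_config()].
#' @return list with `features` (matrix, one row per trial) and `labels`.
#' @export
pipeline_features <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  feats <- t(vapply(dataset$trials,
                    function(tr) process_trace(tr, config)$features,
                    numeric(8)))
  colnames(feats) <- FEATURE_NAMES
  list(features = feats, labels = dataset$manifest$state)
}

#' Run the full recognition pipeline on one trial
#'
#' Conditions the trace, classifies it, and emits the wheelchair command
#' event for the recognized state.
#'
#' @param trace a `labeled_trace` (or a path to a trace CSV).
#' @param model a trained [train_wtsvm()] model.
#' @param config a [pipeline_config()].
#' @return list with `state`, `command` (list with `timestamp`, `state`,
#'   `command`), `score` (decision score V, `NA` for the event-free
#'   short-circuit) and `features`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config()
#' ds <- generate_dataset(30, cfg$trace, seed = 1)
#' fl <- pipeline_features(ds, cfg)
#' model <- train_wtsvm(fl$features, fl$labels, seed = 1)
#' run_pipeline(generate_trial("up", cfg$trace, seed = 5), model, cfg)$command
#' }
#' @export
run_pipeline <- function(trace, model, config = pipeline_config()) {
  if (is.character(trace)) trace <- read_trace(trace)
  if (!inherits(model, "wtsvm_model")) {
    stop("model must be a trained wtsvm_model", call. = FALSE)
  }
  pr <- process_trace(trace, config)
  state <- classify(model, pr$features)
  v <- if (pr$features[["eog_n"]] == 0 && pr$features[["strain_n"]] == 0) {
    NA_real_
  } else {
    decision_score(model, pr$features)
  }
  ts <- trace$t[length(trace$t)]
  list(state = state,
       command = list(timestamp = ts, state = state,
                      command = state_to_command(state)),
       score = v, features = pr$features)
}

#' Dwell-time debouncing for streaming command output
#'
#' For a sequence of per-window state decisions, the emitted command changes
#' only after the new state has persisted for at least `dwell_time` seconds;
#' until then the previous command is held.
#'
#' @param states character vector of per-window states (time order).
#' @param times numeric vector of window timestamps in seconds.
#' @param dwell_time required persistence in seconds (default 0.5).
#' @return character vector of emitted states, same length.
#' @export
dwell_filter <- function(states, times, dwell_time = 0.5) {
  stopifnot(length(states) == length(times))
  check_state(states)
  if (length(states) == 0L) return(character(0))
  out <- character(length(states))
  current <- states[1]
  cand <- current
  cand_since <- times[1]
  for (i in seq_along(states)) {
    if (states[i] != cand) {
      cand <- states[i]
      cand_since <- times[i]
    }
    if (cand != current && times[i] - cand_since >= dwell_time) {
      current <- cand
    }
    out[i] <- current
  }
  out
}
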