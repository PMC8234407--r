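# Shared fixtures, built in code at test time.

# Generator config with every disturbance switched off.
noise_free_config <- function(...) {
  trace_config(powerline_amplitude = 0, white_noise_sd = 0,
               drift_amplitude = 0, ...)
}

noise_free_pipeline <- function(...) {
  pipeline_config(trace = noise_free_config(...))
}

# Small trained model cache: training is cheap but not free, so fixtures
# that need a classifier share one per option set.
.model_cache <- new.env(parent = emptyenv())

fixture_model <- function(n_trials = 50, noise_free = FALSE, seed = 42) {
  key <- paste0("m", n_trials, "_", noise_free, "_", seed)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  cfg <- if (noise_free) noise_free_pipeline() else pipeline_config()
  ds <- generate_dataset(n_trials, cfg$trace, seed = seed)
  fl <- pipeline_features(ds, cfg)
  model <- train_wtsvm(fl$features, fl$labels, seed = seed)
  out <- list(model = model, config = cfg, features = fl$features,
              labels = fl$labels)
  .model_cache[[key]] <- out
  out
}

# Single-sided amplitude spectrum (uniform grid), frequencies in Hz.
amp_spectrum <- function(x, fs) {
  n <- length(x)
  a <- abs(fft(x)) / n
  half <- seq_len(floor(n / 2) + 1)
  amp <- 2 * a[half]
  amp[1] <- a[1]
  list(freq = (half - 1) * fs / n, amp = amp)
}

# Steady-state RMS over the middle half of a series.
mid_rms <- function(x) {
  n <- length(x)
  sqrt(mean(x[seq(floor(n / 4), floor(3 * n / 4))]^2))
}
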