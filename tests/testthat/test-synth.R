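test_that("straight trials are silent and event-free under zero noise", {
  tr <- generate_trial("straight", noise_free_config(), seed = 1)
  expect_true(all(tr$eog == 0))
  expect_true(all(tr$strain_rel == 0))
  expect_equal(nrow(tr$events), 0)
})

test_that("horizontal saccades put one signed spike on the EOG channel only", {
  left <- generate_trial("left", noise_free_config(), seed = 7)
  expect_gte(max(left$eog), 500)
  expect_lte(max(left$eog), 600)
  expect_gte(min(left$eog), 0)
  expect_true(all(left$strain_rel == 0))
  expect_equal(left$events$channel, "eog")

  right <- generate_trial("right", noise_free_config(), seed = 7)
  expect_lte(min(right$eog), -500)
  expect_gte(min(right$eog), -600)
  expect_true(all(right$strain_rel == 0))
})

test_that("vertical gaze perturbs only the strain channel with the configured sign", {
  down <- generate_trial("down", noise_free_config(), seed = 3)
  up <- generate_trial("up", noise_free_config(), seed = 3)
  expect_true(all(down$eog == 0))
  expect_gt(max(down$strain_rel), 0)   # stretch: resistance up
  expect_lt(min(up$strain_rel), 0)     # compression: resistance down
  # flipped convention
  flip <- generate_trial("down", noise_free_config(down_is_stretch = FALSE),
                         seed = 3)
  expect_lt(min(flip$strain_rel), 0)
})

test_that("event bookkeeping respects the trial window", {
  for (s in c("left", "right", "up", "down")) {
    tr <- generate_trial(s, noise_free_config(), seed = 11)
    expect_equal(nrow(tr$events), 1)
    expect_gte(tr$events$onset, 0)
    expect_lte(tr$events$onset + tr$events$duration, 4.0)
  }
})

test_that("seeded generation is bit-for-bit reproducible", {
  a <- generate_trial("left", trace_config(), seed = 42)
  b <- generate_trial("left", trace_config(), seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_trial("left", trace_config(), seed = 43)))
})

test_that("unknown states are rejected by name", {
  expect_error(generate_trial("sideways", trace_config()), "unknown gaze state")
})

test_that("zero noise parameters leave a trace untouched", {
  tr <- generate_trial("left", noise_free_config(), seed = 2)
  out <- add_noise(tr, noise_free_config(), seed = 9)
  expect_equal(out$eog, tr$eog)
  expect_equal(out$strain_rel, tr$strain_rel)
})

test_that("powerline interference lands at exactly 50 Hz with the configured amplitude", {
  cfg <- trace_config(powerline_amplitude = 20, white_noise_sd = 0,
                      drift_amplitude = 0, strain_noise_scale = 0)
  tr <- generate_trial("straight", noise_free_config(), seed = 1)
  noisy <- add_noise(tr, cfg, seed = 5)
  sp <- amp_spectrum(noisy$eog, 250)
  peak <- which.max(sp$amp)
  expect_equal(sp$freq[peak], 50)
  expect_lt(abs(sp$amp[peak] - 20) / 20, 0.01)
})

test_that("rigid mode scales the added noise variance by the factor squared", {
  base <- generate_trial("straight", noise_free_config(), seed = 1)
  flex_cfg <- trace_config(drift_amplitude = 0)
  rigid_cfg <- trace_config(drift_amplitude = 0, electrode_mode = "rigid",
                            rigid_noise_factor = 2.0)
  nf <- add_noise(base, flex_cfg, seed = 8)$eog - base$eog
  nr <- add_noise(base, rigid_cfg, seed = 8)$eog - base$eog
  ratio <- var(nr) / var(nf)
  expect_lt(abs(ratio - 4) / 4, 0.10)
})

test_that("datasets are balanced and manifests deterministic", {
  ds <- generate_dataset(600, trace_config(), seed = 1)
  expect_equal(as.vector(table(ds$manifest$state)), rep(120L, 5))
  ds5 <- generate_dataset(5, trace_config(), seed = 1)
  expect_equal(sort(ds5$manifest$state), sort(gaze_states()))
  expect_identical(generate_dataset(10, trace_config(), seed = 4)$manifest,
                   generate_dataset(10, trace_config(), seed = 4)$manifest)
  expect_error(generate_dataset(4, trace_config()), "at least")
})

test_that("noise-free trials of distinct states are distinguishable by event signature", {
  sig <- vapply(gaze_states(), function(s) {
    tr <- generate_trial(s, noise_free_config(), seed = 21)
    if (nrow(tr$events) == 0) return("none")
    paste0(tr$events$channel, sign(tr$events$amplitude))
  }, character(1))
  expect_equal(length(unique(sig)), 5)
})

test_that("trace and dataset round-trip through CSV", {
  tr <- generate_trial("left", trace_config(), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path, state = "left")
  expect_equal(back$eog, tr$eog, tolerance = 1e-12)
  expect_equal(back$strain_rel, tr$strain_rel, tolerance = 1e-12)
  expect_equal(back$sampling_rate, 250, tolerance = 1e-6)

  ds <- generate_dataset(5, trace_config(), seed = 3)
  dir <- tempfile()
  man <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 5)
  expect_true(all(file.exists(man$path)))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(trace_config(sampling_rate = 80), "exceed 100")
  expect_error(trace_config(eog_spike_amplitude_range = c(600, 500)),
               "low <= high")
  expect_error(trace_config(white_noise_sd = -1), ">= 0")
})
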