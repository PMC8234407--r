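test_that("decomposition of the zero signal is all-zero and dyadic in shape", {
  cfg <- wavelet_config(levels = 5)
  p <- wavelet_decompose(numeric(1024), cfg)
  expect_true(all(p$a == 0))
  expect_true(all(vapply(p$d, function(d) all(d == 0), logical(1))))
  expect_equal(vapply(p$d, length, integer(1)), 1024L / 2L^(1:5))
  expect_equal(length(p$a), 32L)
})

test_that("the transform is orthonormal: impulse energy is preserved", {
  cfg <- wavelet_config(levels = 4)
  x <- c(1, numeric(255))
  p <- wavelet_decompose(x, cfg)
  energy <- sum(p$a^2) + sum(vapply(p$d, function(d) sum(d^2), numeric(1)))
  expect_lt(abs(energy - 1), 1e-8)
})

test_that("a constant series lives entirely in the approximation", {
  cfg <- wavelet_config(levels = 4)
  p <- wavelet_decompose(rep(3, 256), cfg)
  expect_lt(max(abs(unlist(p$d))), 1e-10)
  expect_lt(max(abs(wavelet_reconstruct(p) - 3)), 1e-10)
})

test_that("decompose then reconstruct is exact, including non-dyadic lengths", {
  set.seed(1)
  x <- rnorm(1024)
  p <- wavelet_decompose(x, wavelet_config(levels = 5))
  expect_lt(max(abs(wavelet_reconstruct(p) - x)), 1e-8)
  # 1000-sample trial grid (padded internally)
  y <- rnorm(1000)
  p2 <- wavelet_decompose(y, wavelet_config(levels = 7))
  expect_lt(max(abs(wavelet_reconstruct(p2) - y)), 1e-8)
})

test_that("an all-zero pyramid reconstructs to the zero series", {
  p <- wavelet_decompose(rnorm(256), wavelet_config(levels = 4))
  p$a <- p$a * 0
  for (j in seq_along(p$d)) p$d[[j]] <- p$d[[j]] * 0
  expect_true(all(wavelet_reconstruct(p) == 0))
})

test_that("keeping only the coarse approximation yields a low-frequency series", {
  set.seed(2)
  fs <- 250
  x <- rnorm(1024)
  cfg <- wavelet_config(levels = 5)
  p <- wavelet_decompose(x, cfg)
  for (j in seq_along(p$d)) p$d[[j]] <- p$d[[j]] * 0
  smooth <- wavelet_reconstruct(p)
  sp <- amp_spectrum(smooth, fs)
  band_edge <- fs / 2^6  # nominal approximation band at N = 5
  in_band <- sum(sp$amp[sp$freq <= 2 * band_edge]^2)
  expect_gt(in_band / sum(sp$amp^2), 0.95)
})

test_that("signals too short for the requested depth are rejected", {
  expect_error(wavelet_decompose(rnorm(16), wavelet_config(levels = 5)),
               "too short")
  expect_error(wavelet_config(levels = 4, split_level = 5), "split_level")
})

test_that("inconsistent pyramid shapes are rejected", {
  p <- wavelet_decompose(rnorm(256), wavelet_config(levels = 4))
  p$d[[2]] <- p$d[[2]][-1]
  expect_error(wavelet_reconstruct(p), "inconsistent pyramid")
})

test_that("components of the zero signal are zero and always sum to the input", {
  s <- separate_components(numeric(1000), wavelet_config(), 250)
  expect_true(all(s$strain == 0))
  expect_true(all(s$eog == 0))
  set.seed(4)
  for (state in c("left", "up", "straight")) {
    tr <- generate_trial(state, trace_config(), seed = 17)
    x <- mix_channels(tr)
    s <- separate_components(x, wavelet_config(), 250)
    expect_lt(max(abs(s$strain + s$eog - x)), 1e-6)
  }
})

test_that("a pure slow drift is assigned to the strain component", {
  t <- (0:999) / 250
  x <- 100 * sin(2 * pi * 0.2 * t)
  s <- separate_components(x, wavelet_config(), 250)
  expect_gt(sum(s$strain^2) / (sum(s$strain^2) + sum(s$eog^2)), 0.95)
})

test_that("a compound of saccade pulse and slow plateau separates cleanly", {
  t <- (0:999) / 250
  pulse <- ifelse(t >= 0.5 & t <= 0.75,
                  550 * 0.5 * (1 - cos(2 * pi * (t - 0.5) / 0.25)), 0)
  plat <- 250 * plateau_wave(t)
  comp <- pulse + plat
  s <- separate_components(comp, wavelet_config(), 250)
  expect_gt(cor(s$strain, plat), 0.9)
  expect_gt(cor(s$eog, pulse), 0.9)
  expect_lt(max(abs(s$strain + s$eog - comp)), 1e-6)
})

test_that("raising the split level never increases strain-component energy", {
  # with the saccade mask disabled (floor above any signal level) the strain
  # component is the pure band split, whose kept coefficient set is nested
  t <- (0:999) / 250
  comp <- 250 * plateau_wave(t) +
    ifelse(t >= 2.6 & t <= 2.85,
           550 * 0.5 * (1 - cos(2 * pi * (t - 2.6) / 0.25)), 0)
  energies <- vapply(4:7, function(sl) {
    s <- separate_components(
      comp, wavelet_config(levels = 7, split_level = sl, mask_floor = 1e9),
      250)
    sum(s$strain^2)
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-6 * energies[-length(energies)]))
})

test_that("event channel assignment matches ground truth on noise-free trials", {
  cfg <- noise_free_pipeline()
  states <- rep(c("left", "right", "up", "down"), each = 25)
  ok <- 0
  for (i in seq_along(states)) {
    tr <- generate_trial(states[i], cfg$trace, seed = 1000 + i)
    pr <- process_trace(tr, cfg)
    got <- if (nrow(pr$eog_events) > 0 && nrow(pr$strain_events) == 0) "eog"
           else if (nrow(pr$strain_events) > 0 && nrow(pr$eog_events) == 0) "strain"
           else "ambiguous"
    if (got == tr$events$channel[1]) ok <- ok + 1
  }
  expect_gte(ok / length(states), 0.99)
})
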