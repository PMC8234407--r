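# Orthonormal Daubechies filter bank with 4 vanishing moments (8 taps).
# Standard published constants; the high-pass is the alternating flip.
DB4_LO <- c(-1.0597401785069032e-02,  3.2883011666885197e-02,
             3.0841381835560764e-02, -1.8703481171909309e-01,
            -2.7983769416859854e-02,  6.3088076792985892e-01,
             7.1484657055291567e-01,  2.3037781330889651e-01)
DB4_HI <- c(-2.3037781330889651e-01,  7.1484657055291567e-01,
            -6.3088076792985892e-01, -2.7983769416859854e-02,
             1.8703481171909309e-01,  3.0841381835560764e-02,
            -3.2883011666885197e-02, -1.0597401785069032e-02)

#' Wavelet separation configuration
#'
#' Settings for the multilevel discrete wavelet transform used to split the
#' conditioned compound signal into a slow strain-like component and a fast
#' saccade-like (EOG) component.
#'
#' The split works in two stages.  First the coarse approximation
#' (levels `>= split_level`) gives the slow part of the signal.  Second, a
#' time--scale mask is built from the mid-band detail levels in `mask_band`
#' (about 2--16 Hz at 250 Hz), where a saccade spike concentrates its energy
#' but a slow strain plateau has almost none: time regions whose mid-band
#' envelope (running maximum of the absolute denoised mid-band
#' reconstruction over `mask_window`) exceeds a threshold are attributed to
#' the EOG component, including their share of the slow part.  The threshold
#' is the larger of a noise-adaptive universal threshold (sigma-hat *
#' sqrt(2 log L), sigma-hat from the median absolute deviation of the
#' level-1 details) and the absolute floor `mask_floor` in signal units.
#' The mask is dilated by `mask_dilation` so the sub-1-Hz tail a saccade
#' leaves in the coarse approximation is claimed along with the spike
#' itself.  The two components always sum exactly to the input.
#'
#' @param family wavelet family; only `"db4"` (orthonormal Daubechies,
#'   4 vanishing moments) is built in.
#' @param levels decomposition depth N (default 7 at 250 Hz, so the coarse
#'   approximation covers roughly 0--1 Hz).
#' @param split_level approximation order assigned to the strain component
#'   (default = `levels`).
#' @param threshold_rule `"universal"` (default) or `"fixed"`.
#' @param threshold_mode `"soft"` (default) or `"hard"`; applied to the
#'   detail coefficients when denoising inside [separate_components()].
#' @param fixed_threshold threshold value used when
#'   `threshold_rule = "fixed"`.
#' @param mask_band detail levels used for the saccade-activity mask
#'   (default `4:6`, about 2--16 Hz at 250 Hz).
#' @param mask_floor absolute envelope floor for the mask, in signal units
#'   (default 80; the package pipeline works in uV).
#' @param mask_window envelope window in seconds (default 0.15).
#' @param mask_dilation mask dilation in seconds (default 0.2).
#' @return an object of class `wavelet_config`.
#' @export
wavelet_config <- function(family = "db4",
                           levels = 7,
                           split_level = levels,
                           threshold_rule = c("universal", "fixed"),
                           threshold_mode = c("soft", "hard"),
                           fixed_threshold = 0,
                           mask_band = 4:6,
                           mask_floor = 80,
                           mask_window = 0.15,
                           mask_dilation = 0.2) {
  threshold_rule <- match.arg(threshold_rule)
  threshold_mode <- match.arg(threshold_mode)
  if (!identical(family, "db4")) {
    stop("only the db4 family is built in", call. = FALSE)
  }
  check_scalar(levels, "levels", positive = TRUE)
  check_scalar(split_level, "split_level", positive = TRUE)
  if (split_level > levels) {
    stop("split_level must satisfy 1 <= split_level <= levels", call. = FALSE)
  }
  check_scalar(mask_floor, "mask_floor", nonneg = TRUE)
  check_scalar(mask_dilation, "mask_dilation", nonneg = TRUE)
  structure(
    list(family = family, levels = as.integer(levels),
         split_level = as.integer(split_level),
         threshold_rule = threshold_rule, threshold_mode = threshold_mode,
         fixed_threshold = fixed_threshold,
         mask_band = as.integer(mask_band), mask_floor = mask_floor,
         mask_window = mask_window, mask_dilation = mask_dilation),
    class = "wavelet_config"
  )
}

# One periodized analysis step: x (even length) -> approximation + detail.
dwt_step <- function(x) {
  n <- length(x)
  nh <- n %/% 2L
  a <- numeric(nh)
  d <- numeric(nh)
  k <- 0:(nh - 1L)
  for (m in seq_along(DB4_LO)) {
    idx <- (2L * k + m - 1L) %% n + 1L
    a <- a + DB4_LO[m] * x[idx]
    d <- d + DB4_HI[m] * x[idx]
  }
  list(a = a, d = d)
}

# Inverse of dwt_step (transpose of the orthogonal analysis operator).
idwt_step <- function(a, d) {
  nh <- length(a)
  n <- 2L * nh
  x <- numeric(n)
  k <- 0:(nh - 1L)
  for (m in seq_along(DB4_LO)) {
    idx <- (2L * k + m - 1L) %% n + 1L
    contrib <- DB4_LO[m] * a + DB4_HI[m] * d
    # idx values are distinct within one m (stride 2 mod n)
    x[idx] <- x[idx] + contrib
  }
  x
}

# Symmetric (reflection) padding of x up to length `len`.
reflect_pad <- function(x, len) {
  extra <- len - length(x)
  if (extra == 0L) return(x)
  if (extra > length(x)) stop("padding longer than signal", call. = FALSE)
  c(x, rev(x)[seq_len(extra)])
}

padded_length <- function(n, levels) {
  block <- 2L^levels
  as.integer(ceiling(n / block) * block)
}

#' Multilevel wavelet decomposition
#'
#' Periodized orthonormal db4 analysis.  The signal is first extended to the
#' next multiple of `2^levels` samples by symmetric reflection of its tail,
#' so the transform is orthogonal on the padded signal and
#' [wavelet_reconstruct()] inverts it exactly.
#'
#' @param signal numeric series of length >= `2^levels`.
#' @param config a [wavelet_config()].
#' @return an object of class `wavelet_pyramid`: list with the coarse
#'   approximation `a`, detail coefficient vectors `d[[1]] .. d[[levels]]`
#'   (fine to coarse), the original length `n` and the config.
#' @examples
#' p <- wavelet_decompose(sin(seq(0, 10, length.out = 256)), wavelet_config(levels = 4))
#' max(abs(wavelet_reconstruct(p) - sin(seq(0, 10, length.out = 256))))
#' @export
wavelet_decompose <- function(signal, config = wavelet_config()) {
  stopifnot(inherits(config, "wavelet_config"))
  n <- length(signal)
  if (n < 2^config$levels) {
    stop("signal too short for ", config$levels, " decomposition levels",
         call. = FALSE)
  }
  x <- reflect_pad(signal, padded_length(n, config$levels))
  d <- vector("list", config$levels)
  for (j in seq_len(config$levels)) {
    s <- dwt_step(x)
    d[[j]] <- s$d
    x <- s$a
  }
  structure(list(a = x, d = d, n = n, config = config),
            class = "wavelet_pyramid")
}

#' Reconstruct a series from a wavelet pyramid
#'
#' Inverse of [wavelet_decompose()]; exact to numerical precision when the
#' pyramid is unmodified.
#'
#' @param pyramid a `wavelet_pyramid`.
#' @return numeric series of the original length.
#' @export
wavelet_reconstruct <- function(pyramid) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  a <- pyramid$a
  for (j in rev(seq_along(pyramid$d))) {
    dj <- pyramid$d[[j]]
    if (length(dj) != length(a)) {
      stop("inconsistent pyramid shape at level ", j, call. = FALSE)
    }
    a <- idwt_step(a, dj)
  }
  a[seq_len(pyramid$n)]
}

# Reconstruction keeping only selected parts: the approximation and/or a
# subset of detail levels.
reconstruct_subset <- function(pyramid, keep_approx = TRUE,
                               keep_details = integer(0)) {
  q <- pyramid
  if (!keep_approx) q$a <- q$a * 0
  for (j in seq_along(q$d)) {
    if (!(j %in% keep_details)) q$d[[j]] <- q$d[[j]] * 0
  }
  wavelet_reconstruct(q)
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
hard_threshold <- function(x, thr) x * (abs(x) > thr)

# Centered running maximum over a window of w samples (vectorized over
# shifted copies).
running_max <- function(x, w) {
  n <- length(x)
  h <- w %/% 2L
  out <- x
  for (s in seq_len(h)) {
    out <- pmax(out,
                c(x[-seq_len(s)], rep(x[n], s)),
                c(rep(x[1], s), x[seq_len(n - s)]))
  }
  out
}

# Universal threshold from the finest-scale details.
universal_threshold <- function(pyramid) {
  d1 <- pyramid$d[[1]]
  sigma <- stats::mad(d1, center = 0)
  sigma * sqrt(2 * log(max(length(d1) * 2L, 2L)))
}

#' Separate slow strain and fast EOG components
#'
#' Splits the conditioned compound signal into a slow strain-like component
#' and a fast saccade-like component.  The slow part is the reconstruction
#' from approximation orders `>= split_level`; a time--scale mask built from
#' supra-threshold mid-band detail activity (the saccade signature) hands
#' the slow content under a detected saccade back to the EOG component, so a
#' large spike is not smeared into the strain estimate.  Detail coefficients
#' below the denoising threshold contribute only to the EOG component (the
#' residue channel).  The two outputs always satisfy
#' `strain + eog == signal` up to numerical precision.
#'
#' @param signal numeric series.
#' @param config a [wavelet_config()].
#' @param sampling_rate sampling rate in Hz (used for the mask envelope
#'   window; default 250).
#' @return list with numeric series `strain` and `eog`, and the `mask`
#'   (0--1 weight per sample attributing slow content to the EOG component).
#' @examples
#' t <- (0:999) / 250
#' x <- 250 * plateau_wave(t) # slow plateau only
#' s <- separate_components(x, wavelet_config())
#' sum(s$strain^2) / sum(x^2) # close to 1
#' @export
separate_components <- function(signal, config = wavelet_config(),
                                sampling_rate = 250) {
  stopifnot(inherits(config, "wavelet_config"))
  n <- length(signal)
  pyr <- wavelet_decompose(signal, config)

  # denoising threshold for the detail coefficients
  thr <- switch(config$threshold_rule,
                universal = universal_threshold(pyr),
                fixed = config$fixed_threshold)
  shrink <- if (config$threshold_mode == "soft") soft_threshold else
    hard_threshold

  # slow part: approximation orders >= split_level, i.e. the coarse
  # approximation plus any detail levels above split_level
  coarse_details <- seq_len(config$levels)
  coarse_details <- coarse_details[coarse_details > config$split_level]
  slow <- reconstruct_subset(pyr, keep_approx = TRUE,
                             keep_details = coarse_details)
  fast <- signal - slow

  # saccade-activity mask from denoised mid-band details
  mask_levels <- intersect(config$mask_band, seq_len(config$levels))
  qm <- pyr
  for (j in seq_along(qm$d)) qm$d[[j]] <- shrink(qm$d[[j]], thr)
  mid <- reconstruct_subset(qm, keep_approx = FALSE,
                            keep_details = mask_levels)
  w <- max(1L, round(config$mask_window * sampling_rate))
  env <- running_max(abs(mid), w)
  sigma <- stats::mad(pyr$d[[1]], center = 0)
  mthr <- max(4 * sigma, config$mask_floor)
  m <- as.numeric(env > mthr)
  if (any(m > 0)) {
    # dilate, then smooth the edges with a short Hann taper so the strain
    # component stays continuous
    dil <- max(1L, round(config$mask_dilation * sampling_rate))
    m <- as.numeric(stats::filter(m, rep(1, 2L * dil + 1L), sides = 2) > 0)
    m[is.na(m)] <- 0
    hl <- max(3L, round(0.12 * sampling_rate))
    h <- 0.5 * (1 - cos(2 * pi * seq_len(hl) / (hl + 1)))
    h <- h / sum(h)
    m <- as.numeric(stats::filter(m, h, sides = 2))
    m[is.na(m)] <- 0
    m <- pmin(1, pmax(0, m))
  }
  strain <- (1 - m) * slow
  list(strain = strain, eog = signal - strain, mask = m)
}

#' Reference slow plateau waveform
#'
#' Unit rise--hold--fall plateau (0.6 s half-cosine ramps around a 1.2 s
#' hold, starting at 0.8 s) on the time grid `t`; a convenience ground-truth
#' ingredient for separation examples and tests.
#'
#' @param t time grid in seconds.
#' @return numeric series in `[0, 1]`.
#' @export
plateau_wave <- function(t) {
  plateau_pulse(t, onset = 0.8, rise = 0.6, hold = 1.2, amplitude = 1)
}
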