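#' Analog front-end configuration
#'
#' Parameters of the emulated acquisition circuit: instrumentation amplifier,
#' 48--52 Hz powerline notch, low-pass filter for the sub-10 Hz EOG band, and
#' A/D conversion.  The strain channel is assumed to be conditioned to a
#' voltage proportional to dR/R0 before this chain; `strain_gain_uv` is that
#' divider constant.
#'
#' @param gain amplifier gain (dimensionless, default 1000).
#' @param notch_band two-element stop band in Hz (default `c(48, 52)`).
#' @param lowpass_cutoff low-pass -3 dB cutoff in Hz (default 10; must be
#'   below the notch band).
#' @param adc_bits ADC resolution in bits (8--24, default 12).
#' @param adc_fullscale ADC full scale in volts: the converter spans
#'   `[-adc_fullscale, +adc_fullscale]` after amplification (default 1.65).
#' @param sampling_rate sampling rate in Hz (default 250).
#' @param strain_gain_uv conditioning gain mapping one unit of dR/R0 to
#'   microvolts at the amplifier input (default 12500, i.e. a 2% strain event
#'   appears as 250 uV).
#' @return an object of class `frontend_config`.
#' @export
frontend_config <- function(gain = 1000,
                            notch_band = c(48, 52),
                            lowpass_cutoff = 10,
                            adc_bits = 12,
                            adc_fullscale = 1.65,
                            sampling_rate = 250,
                            strain_gain_uv = 12500) {
  check_scalar(gain, "gain", positive = TRUE)
  check_scalar(lowpass_cutoff, "lowpass_cutoff", positive = TRUE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(adc_fullscale, "adc_fullscale", positive = TRUE)
  check_scalar(strain_gain_uv, "strain_gain_uv", positive = TRUE)
  stopifnot(length(notch_band) == 2, notch_band[1] < notch_band[2])
  if (notch_band[1] <= 0 || notch_band[2] >= sampling_rate / 2) {
    stop("notch band must lie inside (0, sampling_rate/2)", call. = FALSE)
  }
  if (lowpass_cutoff >= notch_band[1]) {
    stop("lowpass_cutoff must be below the notch band", call. = FALSE)
  }
  if (adc_bits < 8 || adc_bits > 24) {
    stop("adc_bits must be in [8, 24]", call. = FALSE)
  }
  structure(
    list(gain = gain, notch_band = notch_band,
         lowpass_cutoff = lowpass_cutoff, adc_bits = adc_bits,
         adc_fullscale = adc_fullscale, sampling_rate = sampling_rate,
         strain_gain_uv = strain_gain_uv),
    class = "frontend_config"
  )
}

# ---- zero-phase IIR filtering -------------------------------------------
#
# signal::filtfilt starts each pass from zero initial conditions, which
# leaves large transients at both ends (a DC series comes back visibly
# distorted).  We therefore run the forward/backward passes ourselves with
# steady-state initial conditions (so constants are exactly invariant) and
# odd-reflection padding that confines residual edge effects to the pads.

# One causal IIR pass started at the steady state for the signal's first
# sample: a constant series maps to exactly dc_gain * constant.
iir_pass <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  y_ss <- x[1] * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init = rep(y_ss, length(a) - 1L)))
}

zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  npad <- min(max(30L * (max(length(a), length(b)) - 1L), 100L), n - 1L)
  if (npad < 1L) stop("signal too short to filter", call. = FALSE)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- iir_pass(b, a, c(pre, x, post))
  y <- rev(iir_pass(b, a, rev(y)))
  y[seq(npad + 1L, npad + n)]
}

#' Instrumentation amplifier
#'
#' Ideal linear amplification of a microvolt series to volts:
#' `out_V = gain * in_uV * 1e-6`.
#'
#' @param signal_uv numeric series in uV.
#' @param gain amplifier gain (> 0).
#' @return numeric series in volts.
#' @examples
#' instrumentation_amplify(rep(500, 3), 1000)  # 0.5 V
#' @export
instrumentation_amplify <- function(signal_uv, gain = 1000) {
  check_scalar(gain, "gain", positive = TRUE)
  gain * signal_uv * 1e-6
}

#' Powerline notch filter
#'
#' Zero-phase (forward--backward) 2nd-order Butterworth band-stop filter
#' rejecting the 50 Hz powerline while leaving the sub-10 Hz EOG band
#' untouched (attenuation at 50 Hz well beyond 30 dB, below 1 dB in the
#' passband).
#'
#' @param signal numeric series.
#' @param sampling_rate sampling rate in Hz.
#' @param band two-element stop band in Hz (default `c(48, 52)`).
#' @return filtered series, same length.
#' @export
notch_filter <- function(signal, sampling_rate, band = c(48, 52)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] <= 0 || band[2] >= sampling_rate / 2) {
    stop("notch band must lie inside (0, Nyquist)", call. = FALSE)
  }
  bf <- signal::butter(2, band / (sampling_rate / 2), type = "stop")
  zero_phase_filter(bf$b, bf$a, signal)
}

#' Low-pass filter
#'
#' Zero-phase 4th-order Butterworth low-pass.  The single-pass cutoff is
#' pre-adjusted analytically so that the forward--backward cascade sits at
#' -3 dB at `cutoff` (a naive double pass would sit at -6 dB there).
#'
#' @param signal numeric series.
#' @param sampling_rate sampling rate in Hz.
#' @param cutoff -3 dB cutoff frequency in Hz (default 10).
#' @return filtered series, same length.
#' @export
lowpass_filter <- function(signal, sampling_rate, cutoff = 10) {
  check_scalar(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= sampling_rate / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  n_order <- 4
  # single pass must be at power 2^(-1/2) at `cutoff` so the double pass is
  # at 1/2; Butterworth prototype in the prewarped (tan) domain:
  tc <- tan(pi * cutoff / sampling_rate) / (sqrt(2) - 1)^(1 / (2 * n_order))
  w_adj <- atan(tc) * 2 / pi  # normalized digital cutoff for butter()
  if (w_adj >= 1) stop("adjusted cutoff exceeds Nyquist", call. = FALSE)
  bf <- signal::butter(n_order, w_adj)
  zero_phase_filter(bf$b, bf$a, signal)
}

#' A/D conversion
#'
#' Uniform mid-rise quantization of a voltage series spanning
#' `[-fullscale, +fullscale]`.  Codes are `floor((v + FS) / (2 FS) * 2^bits)`
#' clipped to `[0, 2^bits - 1]`; the reconstruction maps each code to the
#' center of its quantization cell, so in-range samples are reproduced within
#' half a least-significant step and out-of-range samples clip to the end
#' codes.
#'
#' @param signal_v numeric series in volts.
#' @param bits resolution (>= 2, default 12).
#' @param fullscale half-range in volts (default 1.65).
#' @return list with integer `codes` and the reconstructed `volts` series.
#' @examples
#' adc_quantize(0, bits = 12, fullscale = 1.65)$codes  # 2048
#' @export
adc_quantize <- function(signal_v, bits = 12, fullscale = 1.65) {
  check_scalar(bits, "bits", positive = TRUE)
  if (bits < 2) stop("bits must be >= 2", call. = FALSE)
  check_scalar(fullscale, "fullscale", positive = TRUE)
  nlev <- 2^bits
  codes <- floor((signal_v + fullscale) / (2 * fullscale) * nlev)
  codes <- pmin(pmax(codes, 0), nlev - 1)
  volts <- (codes + 0.5) / nlev * 2 * fullscale - fullscale
  list(codes = as.integer(codes), volts = volts)
}

#' Apply the full acquisition chain
#'
#' Amplify (uV to V), notch out the powerline, low-pass to the EOG band,
#' quantize, and refer the reconstructed voltage back to the input in uV.
#'
#' @param signal_uv numeric series in uV at the electrode.
#' @param config a [frontend_config()].
#' @return conditioned series in uV (same length).
#' @export
apply_frontend <- function(signal_uv, config = frontend_config()) {
  stopifnot(inherits(config, "frontend_config"))
  v <- instrumentation_amplify(signal_uv, config$gain)
  v <- notch_filter(v, config$sampling_rate, config$notch_band)
  v <- lowpass_filter(v, config$sampling_rate, config$lowpass_cutoff)
  q <- adc_quantize(v, config$adc_bits, config$adc_fullscale)
  q$volts / config$gain * 1e6
}
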