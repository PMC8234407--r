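#' Detect supra-threshold events in a component series
#'
#' An event is a maximal run of samples with `|signal| > threshold` lasting
#' at least `min_duration`; shorter runs are discarded.  The event amplitude
#' is the signed extremum inside the run, the duration is the run length,
#' and the interval is the gap from the end of the previous retained event
#' (0 for the first).
#'
#' @param component numeric series (one separated channel).
#' @param t time grid in seconds, same length.
#' @param threshold detection threshold in the channel's units (> 0).
#' @param min_duration minimal event duration in seconds (default 0.05).
#' @return data frame with columns `polarity`, `amplitude`, `onset`,
#'   `duration`, `interval`; zero rows when nothing crosses the threshold.
#' @examples
#' t <- (0:999) / 250
#' x <- ifelse(t > 1 & t < 1.2, 550, 0)
#' detect_events(x, t, threshold = 250)
#' @export
detect_events <- function(component, t, threshold, min_duration = 0.05) {
  check_scalar(threshold, "threshold", positive = TRUE)
  stopifnot(length(component) == length(t))
  above <- abs(component) > threshold
  if (!any(above)) {
    return(data.frame(polarity = integer(), amplitude = numeric(),
                      onset = numeric(), duration = numeric(),
                      interval = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  dt <- t[2] - t[1]
  out <- list()
  prev_end <- NA_real_
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- (i1 - i0 + 1L) * dt
    if (dur < min_duration) next
    seg <- component[i0:i1]
    amp <- seg[which.max(abs(seg))]
    onset <- t[i0]
    interval <- if (is.na(prev_end)) 0 else onset - prev_end
    prev_end <- t[i1] + dt
    out[[length(out) + 1L]] <- data.frame(
      polarity = as.integer(sign(amp)), amplitude = amp,
      onset = onset, duration = dur, interval = interval
    )
  }
  if (length(out) == 0L) {
    return(data.frame(polarity = integer(), amplitude = numeric(),
                      onset = numeric(), duration = numeric(),
                      interval = numeric()))
  }
  do.call(rbind, out)
}

# Per-channel block of the feature vector: signed peak amplitude of the
# largest event, its duration and interval, and the event count.
channel_features <- function(events) {
  if (nrow(events) == 0L) return(c(0, 0, 0, 0))
  i <- which.max(abs(events$amplitude))
  c(events$amplitude[i], events$duration[i], events$interval[i],
    nrow(events))
}

FEATURE_NAMES <- c("eog_amp", "eog_dur", "eog_int", "eog_n",
                   "strain_amp", "strain_dur", "strain_int", "strain_n")

#' Assemble the classifier feature vector
#'
#' Builds the fixed-length 8-vector `(eog amplitude, duration, interval,
#' count, strain amplitude, duration, interval, count)` from the detected
#' events of the two separated components, optionally z-scored with
#' training-set statistics.  Event-free trials encode as the zero vector
#' before normalization.
#'
#' @param eog_events,strain_events event tables from [detect_events()].
#' @param normalizer a [fit_normalizer()] result, or `NULL` for the identity
#'   (raw features).
#' @return named numeric vector of length 8.
#' @export
extract_features <- function(eog_events, strain_events, normalizer = NULL) {
  v <- c(channel_features(eog_events), channel_features(strain_events))
  names(v) <- FEATURE_NAMES
  if (is.null(normalizer)) return(v)
  apply_normalizer(normalizer, matrix(v, nrow = 1,
                                      dimnames = list(NULL, FEATURE_NAMES)))[1, ]
}

#' Feature normalization
#'
#' `fit_normalizer()` computes per-column means and standard deviations of a
#' training feature matrix; `apply_normalizer()` z-scores a matrix with
#' those statistics.  Zero-variance columns are passed through centred but
#' unscaled.  A single Gaussian kernel width acts on all coordinates, so the
#' amplitude (hundreds of uV), duration (fractions of a second) and count
#' features must share a scale.
#'
#' @param x numeric feature matrix (rows = trials).
#' @param normalizer a fitted normalizer.
#' @return `fit_normalizer()`: object of class `feature_normalizer`;
#'   `apply_normalizer()`: matrix of the same shape as `x`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  structure(list(mean = mu, sd = sdev), class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(normalizer, x) {
  if (!inherits(normalizer, "feature_normalizer")) {
    stop("normalizer must be fitted with fit_normalizer()", call. = FALSE)
  }
  x <- as.matrix(x)
  sweep(sweep(x, 2, normalizer$mean, "-"), 2, normalizer$sd, "/")
}

#' Feature extraction settings
#'
#' Detection thresholds for the separated components.  The EOG threshold
#' defaults to 250 uV (half the minimum saccade spike amplitude); the strain
#' threshold to half the nominal plateau magnitude in dR/R0 units.
#'
#' @param eog_threshold_uv EOG component threshold in uV (default 250).
#' @param strain_threshold_rel strain component threshold in dR/R0 units
#'   (default 0.01).
#' @param min_duration minimal event duration in seconds (default 0.05).
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(eog_threshold_uv = 250,
                           strain_threshold_rel = 0.01,
                           min_duration = 0.05) {
  check_scalar(eog_threshold_uv, "eog_threshold_uv", positive = TRUE)
  check_scalar(strain_threshold_rel, "strain_threshold_rel", positive = TRUE)
  check_scalar(min_duration, "min_duration", positive = TRUE)
  structure(list(eog_threshold_uv = eog_threshold_uv,
                 strain_threshold_rel = strain_threshold_rel,
                 min_duration = min_duration),
            class = "feature_config")
}
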