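#' Kalman filter model
#'
#' State-space description used by the per-sample predict/update smoother.
#' The default is the scalar random-walk observation model (A = 1, B = 0,
#' C = 1): each sample is modelled as the previous true value plus process
#' noise of variance `q`, observed with measurement noise of variance `r`.
#' With the generator's default white-noise level (sd 15 uV) the defaults are
#' `q = 1` uV^2 and `r = 225` uV^2.
#'
#' Matrices are accepted for the general multivariate form, but the package
#' pipeline uses the scalar model throughout.
#'
#' @param a state transition (scalar or matrix), default 1.
#' @param b control input coefficient, default 0 (no control).
#' @param c_obs observation coefficient, default 1.
#' @param q process-noise covariance (>= 0), default 1.
#' @param r measurement-noise covariance (> 0), default 225.
#' @param x0 initial state estimate; `NULL` (default) means "first sample"
#'   when filtering a trace.
#' @param p0 initial covariance; `NULL` (default) means `r`.
#' @return an object of class `kalman_model`.
#' @examples
#' m <- kalman_model(q = 1, r = 225)
#' y <- kalman_filter_trace(rnorm(100, 50, 15), m)
#' @export
kalman_model <- function(a = 1, b = 0, c_obs = 1, q = 1, r = 225,
                         x0 = NULL, p0 = NULL) {
  if (any(diag(as.matrix(q)) < 0)) stop("q must be >= 0", call. = FALSE)
  if (any(diag(as.matrix(r)) <= 0)) stop("r must be > 0", call. = FALSE)
  if (!is.null(p0) && any(diag(as.matrix(p0)) < 0)) {
    stop("p0 must be >= 0", call. = FALSE)
  }
  structure(list(a = a, b = b, c_obs = c_obs, q = q, r = r,
                 x0 = x0, p0 = p0),
            class = "kalman_model")
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = length(x), ncol = 1)
}

#' Kalman prediction step
#'
#' Propagates the previous state estimate and covariance through the state
#' model: `x_pred = A x_prev + B u` and `P_pred = A P_prev A' + Q`.
#'
#' @param model a [kalman_model()].
#' @param x_prev previous state estimate.
#' @param p_prev previous covariance.
#' @param u control input (default 0).
#' @return list with `x_pred` and `p_pred`.
#' @examples
#' kalman_predict(kalman_model(q = 0.5), x_prev = 3, p_prev = 1)
#' @export
kalman_predict <- function(model, x_prev, p_prev, u = 0) {
  stopifnot(inherits(model, "kalman_model"))
  A <- as_mat(model$a); B <- as_mat(model$b)
  Q <- as_mat(model$q)
  x_prev <- as_mat(x_prev); p_prev <- as_mat(p_prev)
  if (ncol(A) != nrow(x_prev) || any(dim(p_prev) != dim(Q))) {
    stop("inconsistent shapes in kalman_predict", call. = FALSE)
  }
  x_pred <- A %*% x_prev + B %*% as_mat(u)
  p_pred <- A %*% p_prev %*% t(A) + Q
  list(x_pred = drop(x_pred), p_pred = drop(p_pred))
}

#' Kalman update step
#'
#' Folds a measurement into the prediction:
#' `gain = P_pred C' (C P_pred C' + R)^-1`,
#' `x_post = x_pred + gain (z - C x_pred)`,
#' `P_post = P_pred - gain C P_pred`.
#' In the scalar C = 1 case the gain lies in `[0, 1]`.
#'
#' @param model a [kalman_model()].
#' @param x_pred predicted state.
#' @param p_pred predicted covariance.
#' @param z measurement.
#' @return list with `x_post`, `p_post` and `gain`.
#' @examples
#' kalman_update(kalman_model(r = 1), x_pred = 0, p_pred = 1, z = 2)
#' @export
kalman_update <- function(model, x_pred, p_pred, z) {
  stopifnot(inherits(model, "kalman_model"))
  C <- as_mat(model$c_obs); R <- as_mat(model$r)
  x_pred <- as_mat(x_pred); p_pred <- as_mat(p_pred)
  s <- C %*% p_pred %*% t(C) + R
  if (abs(det(s)) < .Machine$double.xmin) {
    stop("singular innovation covariance", call. = FALSE)
  }
  gain <- p_pred %*% t(C) %*% solve(s)
  x_post <- x_pred + gain %*% (as_mat(z) - C %*% x_pred)
  p_post <- p_pred - gain %*% C %*% p_pred
  list(x_post = drop(x_post), p_post = drop(p_post), gain = drop(gain))
}

#' Filter a sampled series
#'
#' Runs one predict--update cycle per sample (scalar model, vectorized
#' gain recursion).  The initial estimate defaults to the first sample and
#' the initial covariance to `r`, which avoids a start-up transient on short
#' trials.
#'
#' @param signal numeric series (non-empty).
#' @param model a scalar [kalman_model()].
#' @return filtered series of the same length.
#' @export
kalman_filter_trace <- function(signal, model = kalman_model()) {
  stopifnot(inherits(model, "kalman_model"))
  n <- length(signal)
  if (n == 0) stop("empty input series", call. = FALSE)
  a <- as.numeric(model$a); cc <- as.numeric(model$c_obs)
  q <- as.numeric(model$q); r <- as.numeric(model$r)
  if (length(a) != 1L) {
    stop("kalman_filter_trace expects a scalar model", call. = FALSE)
  }
  x <- if (is.null(model$x0)) signal[1] / cc else as.numeric(model$x0)
  p <- if (is.null(model$p0)) r else as.numeric(model$p0)
  out <- numeric(n)
  # The covariance recursion does not depend on the data: precompute the
  # per-sample gains once, then run the state recursion.
  gains <- numeric(n)
  for (i in seq_len(n)) {
    p_pred <- a * p * a + q
    k <- p_pred * cc / (cc * p_pred * cc + r)
    gains[i] <- k
    p <- p_pred - k * cc * p_pred
  }
  for (i in seq_len(n)) {
    x_pred <- a * x
    x <- x_pred + gains[i] * (signal[i] - cc * x_pred)
    out[i] <- x
  }
  out
}
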