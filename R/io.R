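# JSON serialization of configs and trained models.

#' Read and write pipeline configuration as JSON
#'
#' The JSON document mirrors the configuration constructors with sections
#' `trace`, `frontend`, `kalman`, `wavelet`, `features`, `classifier` and
#' top-level `stages`/`dwell_time`; omitted fields take their defaults.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config()`: `path` invisibly;
#'   `read_pipeline_config()`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  payload <- list(
    trace = unclass(config$trace),
    frontend = unclass(config$frontend),
    kalman = unclass(config$kalman),
    wavelet = unclass(config$wavelet),
    features = unclass(config$features),
    classifier = config$classifier,
    stages = as.list(config$stages),
    dwell_time = config$dwell_time
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(ctor, args) {
    args <- args[names(args) %in% names(formals(ctor))]
    do.call(ctor, args)
  }
  tr <- if (is.null(j$trace)) trace_config() else build(trace_config, j$trace)
  fe <- if (is.null(j$frontend)) frontend_config(sampling_rate = tr$sampling_rate)
        else build(frontend_config, j$frontend)
  km <- if (is.null(j$kalman)) kalman_model() else build(kalman_model, j$kalman)
  wc <- if (is.null(j$wavelet)) wavelet_config() else build(wavelet_config, j$wavelet)
  fc <- if (is.null(j$features)) feature_config() else build(feature_config, j$features)
  cl <- list(sigma = NULL, penalty = 1.0, epsilon = 0.05)
  if (!is.null(j$classifier)) cl[names(j$classifier)] <- j$classifier
  stages <- c(frontend = TRUE, kalman = TRUE, wavelet = TRUE)
  if (!is.null(j$stages)) stages[names(j$stages)] <- unlist(j$stages)
  pipeline_config(trace = tr, frontend = fe, kalman = km, wavelet = wc,
                  features = fc, classifier = cl, stages = stages,
                  dwell_time = if (is.null(j$dwell_time)) 0.5 else j$dwell_time)
}

#' Save and load a trained classifier as JSON
#'
#' Serializes the ten binary machines (support vectors, dual coefficients,
#' offsets, class pairs), the kernel width, penalty, boundary tolerance,
#' feature normalizer and interval map, with a format-version field.  The
#' reloaded model predicts identically to the original (the decision
#' functions are evaluated from the stored coefficients).
#'
#' @param model a trained [train_wtsvm()] model.
#' @param path JSON file path.
#' @return `write_model()`: `path` invisibly; `read_model()`: a
#'   `wtsvm_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "wtsvm_model"))
  machines <- lapply(model$machines, function(m) {
    list(classes = as.list(m$classes),
         sv_x = apply(m$sv_x, 1, as.numeric, simplify = FALSE),
         coef = m$coef, b = m$b, orient = m$orient, n_train = m$n_train)
  })
  payload <- list(
    format_version = 1L,
    sigma = model$sigma, penalty = model$penalty, epsilon = model$epsilon,
    normalizer = list(mean = as.list(model$normalizer$mean),
                      sd = as.list(model$normalizer$sd)),
    interval_map = as.list(model$interval_map),
    machines = machines
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$format_version) || j$format_version != 1L) {
    stop("unsupported model format version", call. = FALSE)
  }
  normalizer <- structure(
    list(mean = unlist(j$normalizer$mean), sd = unlist(j$normalizer$sd)),
    class = "feature_normalizer"
  )
  machines <- lapply(j$machines, function(m) {
    list(classes = unlist(m$classes),
         sv_x = do.call(rbind, lapply(m$sv_x, unlist)),
         coef = unlist(m$coef), b = m$b, orient = m$orient,
         n_train = m$n_train)
  })
  structure(
    list(machines = machines, sigma = j$sigma, penalty = j$penalty,
         epsilon = j$epsilon, normalizer = normalizer,
         interval_map = unlist(j$interval_map), format_version = 1L),
    class = "wtsvm_model"
  )
}
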