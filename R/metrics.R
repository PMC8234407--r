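# Column order (actual state) and row order (recognized state) of the
# reversed-row confusion convention: correct predictions sit on the
# anti-diagonal, e.g. cell (1,1) counts actual-straight recognized-as-right.
CONF_COLS <- c("straight", "up", "down", "left", "right")
CONF_ROWS <- rev(CONF_COLS)

#' Build the 5x5 confusion matrix (reversed-row convention)
#'
#' Counts actual-vs-recognized states with columns in the order straight,
#' up, down, left, right and rows in the reverse order (right, left, down,
#' up, straight), so correct recognitions lie on the anti-diagonal: cell
#' `[1, 1]` counts actual straight trials recognized as right.
#'
#' @param actual,predicted character vectors of gaze states, equal length,
#'   non-empty.
#' @return an object of class `gaze_confusion`: the 5x5 count matrix with
#'   dimnames `recognized` x `actual`.
#' @examples
#' m <- build_confusion(c("straight", "up"), c("right", "up"))
#' m["right", "straight"]  # 1
#' @export
build_confusion <- function(actual, predicted) {
  if (length(actual) == 0L) stop("empty inputs", call. = FALSE)
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  check_state(actual)
  check_state(predicted)
  counts <- table(factor(predicted, levels = CONF_ROWS),
                  factor(actual, levels = CONF_COLS))
  m <- matrix(as.integer(counts), nrow = 5, ncol = 5,
              dimnames = list(recognized = CONF_ROWS, actual = CONF_COLS))
  structure(m, class = c("gaze_confusion", "matrix"))
}

#' @export
print.gaze_confusion <- function(x, ...) {
  cat("<gaze_confusion> recognized (rows, reversed) x actual (cols)\n")
  print(unclass(x))
  invisible(x)
}

#' Conventional (diagonal) view of a confusion matrix
#'
#' Re-orders the rows of a reversed-convention matrix so that both rows and
#' columns run straight, up, down, left, right and correct predictions lie
#' on the main diagonal.
#'
#' @param m a `gaze_confusion`.
#' @return plain integer matrix `actual` x `predicted` (diagonal
#'   convention).
#' @export
conventional_confusion <- function(m) {
  stopifnot(inherits(m, "gaze_confusion"))
  t(unclass(m)[rev(seq_len(5)), ])
}

#' Per-state recognition rate
#'
#' The correct recognition rate of the state in column `n` of the
#' reversed-row matrix: the anti-diagonal count `a[6 - n, n]` divided by the
#' column total (the number of trials with that actual state).
#'
#' @param m a `gaze_confusion`.
#' @param n column index 1..5 (1 = straight, ..., 5 = right).
#' @return recognition rate in `[0, 1]`.
#' @export
state_accuracy <- function(m, n) {
  stopifnot(inherits(m, "gaze_confusion"))
  if (!(n %in% 1:5)) stop("n must be in 1..5", call. = FALSE)
  colsum <- sum(m[, n])
  if (colsum == 0) {
    stop("no trials with actual state '", CONF_COLS[n], "'", call. = FALSE)
  }
  m[6 - n, n] / colsum
}

#' Overall recognition accuracy
#'
#' The unweighted mean of the five per-state recognition rates:
#' `accuracy = 0.2 * sum(Sn)`.
#'
#' @param m a `gaze_confusion` with all column sums positive.
#' @return accuracy in `[0, 1]`.
#' @export
overall_accuracy <- function(m) {
  mean(vapply(1:5, function(n) state_accuracy(m, n), numeric(1)))
}

#' Stratified train/test split
#'
#' Splits trial indices into train and test sets with the class proportions
#' preserved per state (each class is split as evenly as the counts allow).
#'
#' @param labels character vector of states.
#' @param train_fraction fraction assigned to training (default 0.5).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.5, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  idx <- with_seed(seed, {
    train <- integer(0)
    for (s in unique(labels)) {
      rows <- which(labels == s)
      k <- round(length(rows) * train_fraction)
      k <- min(max(k, 1L), length(rows) - 1L)
      train <- c(train, sample(rows, k))
    }
    train
  })
  list(train = sort(idx), test = sort(setdiff(seq_along(labels), idx)))
}

#' End-to-end benchmark
#'
#' Mirrors the evaluation protocol of the device study on synthetic data:
#' generate (or accept) a balanced labeled dataset, run every trial through
#' the full pipeline (front end, Kalman, wavelet separation, features),
#' train the one-against-one WT-SVM on a stratified split, classify the
#' held-out half, and report the reversed-convention confusion matrix with
#' per-state and overall accuracies.
#'
#' @param dataset a `gaze_dataset` from [generate_dataset()], or `NULL` to
#'   generate `n_trials` fresh trials.
#' @param config a [pipeline_config()].
#' @param n_trials number of trials when generating (default 600).
#' @param train_fraction stratified split fraction (default 0.5).
#' @param seed master seed (dataset generation, split, training).
#' @return an object of class `gaze_benchmark`: list with `confusion`
#'   (reversed convention), `confusion_conventional`, `per_state` (named
#'   recognition rates), `accuracy`, `n_train`, `n_test`, `seed` and
#'   `timings` (per-stage seconds).
#' @examples
#' \donttest{
#' rep <- run_benchmark(n_trials = 30, seed = 1)
#' rep$accuracy
#' }
#' @export
run_benchmark <- function(dataset = NULL, config = pipeline_config(),
                          n_trials = 600, train_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c(generate = 0, features = 0, train = 0, classify = 0)

  t0 <- proc.time()[["elapsed"]]
  if (is.null(dataset)) {
    dataset <- generate_dataset(n_trials, config$trace, seed = seed)
  }
  timings[["generate"]] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  fl <- pipeline_features(dataset, config)
  timings[["features"]] <- proc.time()[["elapsed"]] - t0

  labels <- fl$labels
  split <- stratified_split(labels, train_fraction,
                            seed = derive_seed(seed, 101L))
  if (length(unique(labels[split$train])) < length(GAZE_STATES) ||
      length(unique(labels[split$test])) < length(GAZE_STATES)) {
    stop("every class must appear in both splits", call. = FALSE)
  }

  t0 <- proc.time()[["elapsed"]]
  model <- train_wtsvm(fl$features[split$train, , drop = FALSE],
                       labels[split$train],
                       sigma = config$classifier$sigma,
                       penalty = config$classifier$penalty,
                       epsilon = config$classifier$epsilon,
                       seed = derive_seed(seed, 202L))
  timings[["train"]] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  predicted <- predict_states(model, fl$features[split$test, , drop = FALSE])
  timings[["classify"]] <- proc.time()[["elapsed"]] - t0

  confusion <- build_confusion(labels[split$test], predicted)
  per_state <- stats::setNames(
    vapply(1:5, function(n) state_accuracy(confusion, n), numeric(1)),
    CONF_COLS
  )
  structure(
    list(confusion = confusion,
         confusion_conventional = conventional_confusion(confusion),
         per_state = per_state,
         accuracy = overall_accuracy(confusion),
         n_train = length(split$train), n_test = length(split$test),
         seed = seed, stages = config$stages, timings = timings,
         model = model),
    class = "gaze_benchmark"
  )
}

#' @export
print.gaze_benchmark <- function(x, ...) {
  cat("<gaze_benchmark> accuracy=", sprintf("%.1f%%", 100 * x$accuracy),
      " (train ", x$n_train, " / test ", x$n_test, ", seed ", x$seed, ")\n",
      sep = "")
  cat("per-state: ",
      paste(sprintf("%s=%.1f%%", names(x$per_state), 100 * x$per_state),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a benchmark report
#'
#' Writes the report as JSON (accuracy, per-state rates, split sizes, seed,
#' stage flags) plus the confusion matrix as a labelled CSV in both
#' conventions.
#'
#' @param report a `gaze_benchmark`.
#' @param path output JSON path; the confusion CSVs are written next to it
#'   with suffixes `_confusion.csv` (reversed) and
#'   `_confusion_conventional.csv`.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  stopifnot(inherits(report, "gaze_benchmark"))
  payload <- list(
    accuracy = report$accuracy,
    per_state = as.list(report$per_state),
    n_train = report$n_train, n_test = report$n_test,
    seed = report$seed, stages = as.list(report$stages)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  base <- sub("\\.json$", "", path)
  write.csv(as.data.frame(unclass(report$confusion)),
            paste0(base, "_confusion.csv"))
  write.csv(as.data.frame(report$confusion_conventional),
            paste0(base, "_confusion_conventional.csv"))
  invisible(path)
}
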