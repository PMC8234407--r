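#' Gaussian (RBF) kernel
#'
#' Similarity `exp(-||x - x'||^2 / (2 sigma^2))`: symmetric, in `(0, 1]`,
#' and equal to 1 exactly when the two vectors coincide.  This kernel is the
#' package's own implementation and is the only kernel the classifier uses.
#'
#' @param x,x_prime numeric vectors of equal length.
#' @param sigma kernel width (> 0).
#' @return scalar similarity in `(0, 1]`.
#' @examples
#' gaussian_kernel(c(1, 0), c(1, 0), sigma = 1)        # 1
#' gaussian_kernel(c(0, 0), c(1, 1), sigma = 1)        # exp(-1)
#' @export
gaussian_kernel <- function(x, x_prime, sigma) {
  check_scalar(sigma, "sigma", positive = TRUE)
  if (length(x) != length(x_prime)) {
    stop("x and x_prime must have equal length", call. = FALSE)
  }
  exp(-sum((x - x_prime)^2) / (2 * sigma^2))
}

#' @rdname gaussian_kernel
#' @param a,b numeric matrices (rows = observations) with matching column
#'   counts.
#' @return `gaussian_kernel_matrix()`: the `nrow(a)` x `nrow(b)` kernel
#'   matrix.
#' @export
gaussian_kernel_matrix <- function(a, b, sigma) {
  check_scalar(sigma, "sigma", positive = TRUE)
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# Interval midpoints of the decision rule: V in (0,1) -> up, (-1,0) -> down,
# (1,2) -> left, (-2,-1) -> right; boundaries (and vote ties) -> straight.
INTERVAL_MIDPOINT <- c(straight = 0, up = 0.5, down = -0.5,
                       left = 1.5, right = -1.5)
INTERVAL_BOUNDARIES <- c(-2, -1, 0, 1, 2)

# Median pairwise distance heuristic for the kernel width.
median_heuristic_sigma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  s <- stats::median(d[d > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Train the one-against-one WT-SVM classifier
#'
#' Trains the `C(5,2) = 10` binary Gaussian-kernel support vector machines
#' over the five gaze states.  Kernel values are computed exclusively by the
#' package's [gaussian_kernel_matrix()]; the quadratic-programming solution
#' of each binary subproblem is delegated to `kernlab::ksvm` on the
#' precomputed kernel matrix.  Features are z-scored with statistics fitted
#' on the training set.
#'
#' @param features numeric feature matrix (rows = trials, 8 columns as
#'   produced by [extract_features()]).
#' @param labels character vector of gaze states, one per row.
#' @param sigma Gaussian kernel width; `NULL` (default) uses the median
#'   pairwise distance heuristic on the normalized training features.
#' @param penalty SVM cost parameter C (default 1).
#' @param epsilon boundary tolerance of the interval decision rule
#'   (default 0.05).
#' @param seed integer seed (kernel-width subsampling and solver).
#' @return an object of class `wtsvm_model` with the ten binary machines,
#'   the kernel width, the feature normalizer and the interval map.
#' @examples
#' \donttest{
#' ds <- generate_dataset(30, trace_config(), seed = 1)
#' feats <- pipeline_features(ds, pipeline_config())
#' m <- train_wtsvm(feats$features, feats$labels, seed = 1)
#' classify(m, feats$features[1, ])
#' }
#' @export
train_wtsvm <- function(features, labels, sigma = NULL, penalty = 1.0,
                        epsilon = 0.05, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  check_state(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels must have matching lengths", call. = FALSE)
  }
  missing_cls <- setdiff(GAZE_STATES, labels)
  if (length(missing_cls) > 0) {
    stop("missing class(es) in training data: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("each class needs at least 2 training samples", call. = FALSE)
  }
  check_scalar(penalty, "penalty", positive = TRUE)
  check_scalar(epsilon, "epsilon", nonneg = TRUE)

  normalizer <- fit_normalizer(features)
  xz <- apply_normalizer(normalizer, features)

  pairs <- utils::combn(GAZE_STATES, 2, simplify = FALSE)
  machines <- with_seed(seed, {
    if (is.null(sigma)) sigma <- median_heuristic_sigma(xz)
    lapply(pairs, function(pr) {
      rows <- which(labels %in% pr)
      xi <- xz[rows, , drop = FALSE]
      yi <- factor(labels[rows], levels = pr)
      K <- gaussian_kernel_matrix(xi, xi, sigma)
      fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yi, C = penalty)
      sv <- kernlab::SVindex(fit)
      sv_x <- xi[sv, , drop = FALSE]
      coef <- as.numeric(kernlab::coef(fit)[[1]])
      b <- as.numeric(kernlab::b(fit))
      # pin down the sign convention of the stored decision function by
      # comparing it with kernlab's own predictions on the training rows
      Ksv <- K[, sv, drop = FALSE]
      dec <- as.numeric(Ksv %*% coef - b)
      pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(Ksv))
      orient <- if (mean((dec > 0) == (as.character(pred) == pr[2])) >= 0.5)
        1 else -1
      list(classes = pr, sv_x = sv_x, coef = coef, b = b, orient = orient,
           n_train = length(rows))
    })
  })

  structure(
    list(machines = machines, sigma = sigma, penalty = penalty,
         epsilon = epsilon, normalizer = normalizer,
         interval_map = INTERVAL_MIDPOINT, format_version = 1L),
    class = "wtsvm_model"
  )
}

#' @export
print.wtsvm_model <- function(x, ...) {
  cat("<wtsvm_model> ", length(x$machines),
      " one-against-one Gaussian-kernel SVMs, sigma=",
      signif(x$sigma, 4), ", C=", x$penalty, ", epsilon=", x$epsilon, "\n",
      sep = "")
  invisible(x)
}

# Decision value of one binary machine for normalized feature rows.
machine_decision <- function(machine, xz, sigma) {
  K <- gaussian_kernel_matrix(xz, machine$sv_x, sigma)
  machine$orient * (as.numeric(K %*% machine$coef) - machine$b)
}

# Vote counts of the ten binary machines for one normalized feature vector.
ovo_votes <- function(model, xz) {
  votes <- stats::setNames(numeric(length(GAZE_STATES)), GAZE_STATES)
  for (m in model$machines) {
    dec <- machine_decision(m, xz, model$sigma)[1]
    winner <- if (dec > 0) m$classes[2] else m$classes[1]
    votes[winner] <- votes[winner] + 1
  }
  votes
}

normalize_input <- function(model, x) {
  x <- matrix(as.numeric(x), nrow = 1)
  apply_normalizer(model$normalizer, x)
}

#' Interval decision score
#'
#' Aggregates the ten one-against-one votes to the scalar decision score V.
#' The vote share is normalized hard: the majority class receives weight 1
#' and V is the midpoint of its decision interval (up +0.5, down -0.5,
#' left +1.5, right -1.5, straight 0); a tie in the vote maximum yields
#' V = 0.  V therefore always lies in `[-2, 2]`, and a pure vote pattern for
#' a directional state lands exactly at its interval midpoint.
#'
#' @param model a trained [train_wtsvm()] model.
#' @param x raw (unnormalized) feature vector of length 8.
#' @return scalar decision score V.
#' @export
decision_score <- function(model, x) {
  if (!inherits(model, "wtsvm_model")) {
    stop("model must be a trained wtsvm_model", call. = FALSE)
  }
  votes <- ovo_votes(model, normalize_input(model, x))
  score_from_votes(votes, model$interval_map)
}

# Shared vote -> V aggregation (exposed internally for tests of pure vote
# patterns).
score_from_votes <- function(votes, interval_map = INTERVAL_MIDPOINT) {
  top <- max(votes)
  leaders <- names(votes)[votes == top]
  if (length(leaders) != 1L) return(0)
  unname(interval_map[leaders])
}

#' Classify a feature vector
#'
#' Applies the interval decision rule to the score V: a score inside an open
#' interval selects its state; a score within `epsilon` of an interval
#' boundary (-2, -1, 0, 1, 2) means straight gaze.  Trials whose feature
#' vector records no event on either channel short-circuit to straight.
#'
#' @param model a trained [train_wtsvm()] model.
#' @param x raw feature vector of length 8.
#' @return one of the five gaze states.
#' @export
classify <- function(model, x) {
  if (!inherits(model, "wtsvm_model")) {
    stop("model must be a trained wtsvm_model", call. = FALSE)
  }
  x <- as.numeric(x)
  # event-free trial: no event on either channel
  if (x[4] == 0 && x[8] == 0) return("straight")
  v <- decision_score(model, x)
  state_from_score(v, model$epsilon)
}

# Map a score V to a state under the interval rule.
state_from_score <- function(v, epsilon = 0.05) {
  if (any(abs(v - INTERVAL_BOUNDARIES) <= epsilon)) return("straight")
  if (v > 0 && v < 1) return("up")
  if (v > -1 && v < 0) return("down")
  if (v > 1 && v < 2) return("left")
  if (v > -2 && v < -1) return("right")
  "straight"
}

#' Batch prediction
#'
#' Classifies each row of a feature matrix.
#'
#' @param model a trained [train_wtsvm()] model.
#' @param features numeric feature matrix (rows = trials).
#' @return character vector of predicted gaze states.
#' @export
predict_states <- function(model, features) {
  features <- as.matrix(features)
  vapply(seq_len(nrow(features)),
         function(i) classify(model, features[i, ]), character(1))
}
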