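test_that("the Gaussian kernel has its closed-form values and symmetry", {
  x <- c(1, 2, 3)
  expect_equal(gaussian_kernel(x, x, sigma = 2), 1.0)
  # distance sigma * sqrt(2) -> exp(-1)
  a <- c(0, 0); b <- c(2, 0)
  expect_equal(gaussian_kernel(a, b, sigma = sqrt(2)), exp(-1))
  set.seed(1)
  for (i in 1:10) {
    u <- rnorm(8); v <- rnorm(8)
    expect_equal(gaussian_kernel(u, v, 1.3), gaussian_kernel(v, u, 1.3))
    expect_gt(gaussian_kernel(u, v, 1.3), 0)
    expect_lte(gaussian_kernel(u, v, 1.3), 1)
  }
  expect_error(gaussian_kernel(a, b, sigma = 0), "> 0")
  expect_error(gaussian_kernel(c(1, 2), c(1, 2, 3), 1), "equal length")
})

test_that("the kernel matrix agrees with the scalar kernel entrywise", {
  set.seed(2)
  A <- matrix(rnorm(24), nrow = 3)
  B <- matrix(rnorm(16), nrow = 2)
  K <- gaussian_kernel_matrix(A, B, sigma = 1.7)
  for (i in 1:3) for (j in 1:2) {
    expect_equal(K[i, j], gaussian_kernel(A[i, ], B[j, ], 1.7),
                 tolerance = 1e-12)
  }
})

test_that("training builds exactly ten pairwise machines and separates clean data", {
  fx <- fixture_model(n_trials = 100, noise_free = TRUE)
  expect_equal(length(fx$model$machines), 10L)
  pairs <- vapply(fx$model$machines,
                  function(m) paste(m$classes, collapse = "-"), character(1))
  expect_equal(length(unique(pairs)), 10L)
  pred <- predict_states(fx$model, fx$features)
  expect_gte(mean(pred == fx$labels), 0.95)
})

test_that("training is deterministic for a fixed seed", {
  fx <- fixture_model(n_trials = 50, noise_free = TRUE)
  m2 <- train_wtsvm(fx$features, fx$labels, seed = 42)
  expect_equal(fx$model$sigma, m2$sigma)
  expect_identical(predict_states(fx$model, fx$features),
                   predict_states(m2, fx$features))
})

test_that("duplicating every training sample leaves the decision function unchanged", {
  fx <- fixture_model(n_trials = 50, noise_free = TRUE)
  dup <- train_wtsvm(rbind(fx$features, fx$features),
                     c(fx$labels, fx$labels),
                     sigma = fx$model$sigma, seed = 42)
  v1 <- vapply(seq_len(nrow(fx$features)),
               function(i) decision_score(fx$model, fx$features[i, ]),
               numeric(1))
  v2 <- vapply(seq_len(nrow(fx$features)),
               function(i) decision_score(dup, fx$features[i, ]),
               numeric(1))
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("missing classes and short classes are rejected by name", {
  fx <- fixture_model(n_trials = 50, noise_free = TRUE)
  keep <- fx$labels != "up"
  expect_error(train_wtsvm(fx$features[keep, ], fx$labels[keep]),
               "missing class.*up")
})

test_that("pure vote patterns land exactly on the interval midpoints", {
  votes <- function(...) {
    v <- stats::setNames(numeric(5), gaze_states())
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  # a clean winner takes its full interval midpoint
  expect_equal(gazekit:::score_from_votes(votes(left = 4, up = 2, down = 2,
                                                right = 1, straight = 1)), 1.5)
  expect_equal(gazekit:::score_from_votes(votes(right = 4, up = 2, down = 2,
                                                left = 1, straight = 1)), -1.5)
  expect_equal(gazekit:::score_from_votes(votes(up = 4, down = 3, left = 1,
                                                right = 1, straight = 1)), 0.5)
  expect_equal(gazekit:::score_from_votes(votes(down = 4, up = 3, left = 1,
                                                right = 1, straight = 1)), -0.5)
  # uniform share over the four directions: midpoints cancel to 0
  expect_equal(gazekit:::score_from_votes(votes(up = 2, down = 2, left = 2,
                                                right = 2, straight = 2)), 0)
  # straight majority
  expect_equal(gazekit:::score_from_votes(votes(straight = 4, up = 2,
                                                down = 2, left = 1,
                                                right = 1)), 0)
})

test_that("the interval rule maps scores to states with a straight boundary band", {
  expect_equal(gazekit:::state_from_score(0.5), "up")
  expect_equal(gazekit:::state_from_score(-0.5), "down")
  expect_equal(gazekit:::state_from_score(1.5), "left")
  expect_equal(gazekit:::state_from_score(-1.5), "right")
  expect_equal(gazekit:::state_from_score(0), "straight")
  expect_equal(gazekit:::state_from_score(1.02, epsilon = 0.05), "straight")
  expect_equal(gazekit:::state_from_score(1.08, epsilon = 0.05), "left")
})

test_that("decision scores of clean trials sit inside their decision intervals", {
  fx <- fixture_model(n_trials = 100, noise_free = TRUE)
  intervals <- list(up = c(0, 1), down = c(-1, 0), left = c(1, 2),
                    right = c(-2, -1))
  for (s in names(intervals)) {
    rows <- which(fx$labels == s)[1:5]
    for (i in rows) {
      v <- decision_score(fx$model, fx$features[i, ])
      expect_gt(v, intervals[[s]][1])
      expect_lt(v, intervals[[s]][2])
    }
  }
})

test_that("event-free feature vectors short-circuit to straight", {
  fx <- fixture_model(n_trials = 50, noise_free = TRUE)
  expect_equal(classify(fx$model, rep(0, 8)), "straight")
  expect_error(classify(list(), rep(0, 8)), "trained")
  expect_error(decision_score(list(), rep(0, 8)), "trained")
})

test_that("relabelling left and right permutes the predictions accordingly", {
  fx <- fixture_model(n_trials = 100, noise_free = TRUE)
  swap <- function(l) ifelse(l == "left", "right",
                             ifelse(l == "right", "left", l))
  m_sw <- train_wtsvm(fx$features, swap(fx$labels),
                      sigma = fx$model$sigma, seed = 42)
  p0 <- predict_states(fx$model, fx$features)
  p_sw <- predict_states(m_sw, fx$features)
  expect_equal(p_sw, swap(p0))
})

test_that("a trained model survives the JSON round trip with identical predictions", {
  fx <- fixture_model(n_trials = 50, noise_free = TRUE)
  path <- tempfile(fileext = ".json")
  write_model(fx$model, path)
  back <- read_model(path)
  expect_equal(back$sigma, fx$model$sigma)
  expect_identical(predict_states(back, fx$features),
                   predict_states(fx$model, fx$features))
  v1 <- decision_score(fx$model, fx$features[1, ])
  v2 <- decision_score(back, fx$features[1, ])
  expect_equal(v1, v2, tolerance = 1e-12)
})
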