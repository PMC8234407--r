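# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state so seeded generation is
# reproducible without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; stays within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1009) %% 2147483647)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop(name, " must be >= 0", call. = FALSE)
  invisible(x)
}
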