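# Internal helpers shared across modules.

#' Derive a child seed from a parent seed
#'
#' Expands one global seed into independent per-module seeds with a
#' documented counter scheme (multiplicative congruential step modulo
#' 2^31 - 1), so each stage of a pipeline is reproducible on its own.
#'
#' @param seed Parent integer seed.
#' @param index Non-negative counter selecting the child stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 1)
child_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + as.numeric(index) * 12345 + 1) %% m
  as.integer(s)
}

# Evaluate expr under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Pairwise Euclidean distance matrix for an n x 2 coordinate matrix.
pair_dist <- function(pos) {
  as.matrix(stats::dist(pos))
}

# Wrap angles in degrees into [0, 360).
wrap360 <- function(a) ((a %% 360) + 360) %% 360

# Wrap orientations in degrees into [0, 180).
wrap180 <- function(a) ((a %% 180) + 180) %% 180

# Smallest signed difference between two orientations (degrees, result
# in (-90, 90]).
op_diff <- function(a, b) {
  d <- wrap180(a - b)
  ifelse(d > 90, d - 180, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
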