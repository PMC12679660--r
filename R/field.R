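#' Build a neural field: geometry plus initial gain state
#'
#' Constructs the simulated network substrate: soma positions,
#' excitatory/inhibitory labels, the integer conduction-delay matrix
#' derived from pairwise distance and conduction speed, and the initial
#' three-timescale signed gain matrices masked by a seeded random
#' connection topology.
#'
#' The delay between a presynaptic neuron `j` and a postsynaptic neuron
#' `i` is `round(|pos_i - pos_j| / (v * dt))` time steps.  Connection
#' probability between two neurons at distance `d` is
#' `density * exp(-d / sigma)` (set `sigma = Inf` for distance-free
#' Erdos-Renyi wiring).  Unless `single_population = TRUE`, every neuron
#' is guaranteed at least one excitatory and one inhibitory afferent
#' (the nearest candidate is wired in if the random draw left none), so
#' that excitatory/inhibitory flux balancing is achievable.
#'
#' @param config A list with elements
#'   \describe{
#'     \item{n}{number of neurons (>= 2).}
#'     \item{layout}{`"grid"` (default) or `"random"` soma placement, or
#'       supply `positions` directly.}
#'     \item{positions}{optional `n x 2` coordinate matrix.}
#'     \item{spacing}{grid spacing / domain scale, default 1.}
#'     \item{frac_excitatory}{fraction of excitatory neurons, default 0.75.}
#'     \item{v}{conduction speed (length units per step), > 0.}
#'     \item{dt}{time step, default 1.}
#'     \item{connection}{list(density, sigma): base connection probability
#'       and distance decay scale.}
#'     \item{gains}{list(eps0, g0, g_sd, rho0): initial gain levels.}
#'     \item{single_population}{allow a field without both cell types.}
#'     \item{seed}{integer seed for topology and initial gains.}
#'   }
#' @return A list of class `neural_field` with elements `geometry`
#'   (class `field_geometry`) and `gains` (class `gain_state`).
#' @export
#' @examples
#' f <- build_field(list(n = 16, v = 1, seed = 1))
#' dim(f$geometry$delay)
build_field <- function(config) {
  cfg <- merge_defaults(config, default_field_config())
  n <- as.integer(cfg$n)
  if (is.null(n) || n < 2) stop("invalid parameter: n must be >= 2")
  if (!is.finite(cfg$v) || cfg$v <= 0)
    stop("invalid parameter: conduction speed v must be > 0")
  if (!is.finite(cfg$dt) || cfg$dt <= 0)
    stop("invalid parameter: dt must be > 0")
  dens <- cfg$connection$density
  if (!is.finite(dens) || dens <= 0 || dens > 1)
    stop("invalid parameter: connection density must be in (0, 1]")
  if (is.null(cfg$seed)) stop("invalid parameter: seed is required")

  if (!is.null(cfg$positions)) {
    pos <- as.matrix(cfg$positions)
    if (nrow(pos) != n || ncol(pos) != 2)
      stop("invalid geometry: positions must be an n x 2 matrix")
  } else if (identical(cfg$layout, "grid")) {
    side <- ceiling(sqrt(n))
    g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n), ]
    pos <- as.matrix(g) * cfg$spacing
  } else {
    side <- sqrt(n) * cfg$spacing
    pos <- with_seed(child_seed(cfg$seed, 7L),
                     matrix(stats::runif(2 * n, 0, side), ncol = 2))
  }
  if (any(!is.finite(pos))) stop("invalid geometry: non-finite positions")

  n_e <- round(cfg$frac_excitatory * n)
  if (!cfg$single_population) n_e <- min(max(n_e, 1L), n - 1L)
  # interleave inhibitory cells through the patch
  ei <- rep("E", n)
  if (n_e < n) ei[unique(round(seq(n, 1, length.out = n - n_e)))] <- "I"

  D <- pair_dist(pos)
  delay <- matrix(as.integer(round(D / (cfg$v * cfg$dt))), n, n)
  diag(delay) <- 0L

  # Seeded random topology with distance-decaying probability.
  # Excitatory axons are local (sigma); inhibitory interneurons project
  # densely across the whole patch (density_i, sigma_i), the shared
  # inhibition that paces a common rhythm.
  sigma <- cfg$connection$sigma
  dens_i <- cfg$connection$density_i %||% 1
  sigma_i <- cfg$connection$sigma_i %||% Inf
  pcol <- function(dd, ss) if (is.finite(ss)) dd * exp(-D / ss)
                           else matrix(dd, n, n)
  pmat <- pcol(dens, sigma)
  icols <- ei == "I"
  pmat[, icols] <- pcol(dens_i, sigma_i)[, icols]
  diag(pmat) <- 0
  # Couplings are bidirectional: signal exchange is reciprocal, the
  # precondition for even (zero-lag peaked) cross-correlations.
  u <- with_seed(child_seed(cfg$seed, 11L), matrix(stats::runif(n * n), n, n))
  u[lower.tri(u)] <- t(u)[lower.tri(u)]
  mask <- u < pmat
  diag(mask) <- FALSE

  if (!cfg$single_population) {
    # Guarantee each neuron one excitatory and one inhibitory afferent
    # (added reciprocally to keep the topology bidirectional).
    for (typ in c("E", "I")) {
      cand <- which(ei == typ)
      for (i in seq_len(n)) {
        if (!any(mask[i, cand])) {
          ok <- setdiff(cand, i)
          j <- ok[which.min(D[i, ok])]
          mask[i, j] <- TRUE
          mask[j, i] <- TRUE
        }
      }
    }
  }

  sgn <- matrix(rep(ifelse(ei == "E", 1, -1), each = n), n, n)
  gcf <- cfg$gains
  g0 <- with_seed(child_seed(cfg$seed, 13L),
                  matrix(abs(stats::rnorm(n * n, gcf$g0, gcf$g_sd)), n, n))
  g0[lower.tri(g0)] <- t(g0)[lower.tri(g0)]   # symmetric exchange strengths
  if (!cfg$single_population) {
    # start balanced: rescale each neuron's inhibitory afferent block so
    # summed inhibitory gain matches summed excitatory gain (the
    # excitatory/inhibitory flux balance is a standing constraint of the
    # steady state, maintained later by anti-Hebbian normalization)
    ecol <- ei == "E"
    se <- rowSums((g0 * mask)[, ecol, drop = FALSE])
    si <- rowSums((g0 * mask)[, !ecol, drop = FALSE])
    ok <- si > 0
    g0[ok, !ecol] <- g0[ok, !ecol] * (se[ok] / si[ok])
  }
  gains <- structure(list(
    eps = cfg$gains$eps0 * mask,
    g = g0 * mask,
    rho = gcf$rho0 * mask,
    sign = sgn,
    mask = mask,
    eps0 = gcf$eps0,
    row_budget = NULL
  ), class = "gain_state")
  gains$row_budget <- rowSums(gains$g) * cfg$gains$headroom

  geometry <- structure(list(
    n = n, positions = pos, ei = ei, v = cfg$v, dt = cfg$dt,
    delay = delay, single_population = cfg$single_population
  ), class = "field_geometry")

  structure(list(geometry = geometry, gains = gains, config = cfg),
            class = "neural_field")
}

default_field_config <- function() {
  list(
    n = 64L,
    layout = "grid",
    positions = NULL,
    spacing = 1,
    frac_excitatory = 0.75,
    v = 3,
    dt = 1,
    connection = list(density = 0.8, sigma = 3, density_i = 1,
                      sigma_i = Inf),
    gains = list(eps0 = 1, g0 = 0.03, g_sd = 0.012, rho0 = 1, headroom = 2),
    single_population = FALSE,
    seed = NULL
  )
}

# Recursive default merge; unknown keys in x are kept (validated by the
# config loader, not here).
merge_defaults <- function(x, defaults) {
  if (is.null(x)) return(defaults)
  for (k in names(defaults)) {
    if (is.null(x[[k]])) {
      x[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(x[[k]]) &&
               !is.null(names(defaults[[k]]))) {
      x[[k]] <- merge_defaults(x[[k]], defaults[[k]])
    }
  }
  x
}

#' Seeded white-noise drive
#'
#' Generates the temporally and spatially uncorrelated zero-mean input
#' field sampled at neuron positions: i.i.d. Gaussian samples with
#' standard deviation `amplitude`, bit-reproducible from `seed`.
#'
#' @param n Number of neurons.
#' @param steps Number of time steps (>= 1).
#' @param amplitude Standard deviation in flux units (>= 0).
#' @param seed Integer seed.
#' @return A `steps x n` matrix of class `drive_signal` with attributes
#'   `amplitude` and `seed`.
#' @export
#' @examples
#' d <- white_noise_drive(4, 100, amplitude = 0.2, seed = 1)
white_noise_drive <- function(n, steps, amplitude, seed) {
  stopifnot(n >= 1)
  if (steps < 1) stop("invalid parameter: steps must be >= 1")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("invalid parameter: amplitude must be >= 0")
  samples <- with_seed(seed,
                       matrix(stats::rnorm(steps * n, 0, 1), steps, n) * amplitude)
  structure(samples, amplitude = amplitude, seed = as.integer(seed),
            class = c("drive_signal", "matrix", "array"))
}
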