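# Lagged correlation matrices: element [i, j] of the k-th slice is
# cor(x_i(t), x_j(t + k)), k = 0..lag_max, computed with window-wide
# centering and scaling.  Returns a list of (n x n) matrices.
lagged_cor <- function(X, lag_max) {
  L <- nrow(X)
  if (lag_max >= L) stop("insufficient-data error: lag range >= window length")
  Xc <- sweep(X, 2, colMeans(X))
  sds <- sqrt(colMeans(Xc^2))
  sds[sds == 0] <- NA_real_
  lapply(0:lag_max, function(k) {
    Ck <- crossprod(Xc[seq_len(L - k), , drop = FALSE],
                    Xc[k + seq_len(L - k), , drop = FALSE]) / (L - k)
    Ck / tcrossprod(sds)
  })
}

#' Zero-lag synchrony index of a multichannel record
#'
#' The fraction of channel pairs whose cross-correlation function, over
#' lags `-lag_max..lag_max`, attains its maximum at lag zero (ties are
#' counted as zero lag).  This is the operational statistic for
#' zero-lag synchronous oscillation: it approaches 1 as the field
#' converges to synchrony and is near `1/(2 lag_max + 1)` for unrelated
#' channels.
#'
#' @param x A `simulation_record` (pulse rates are used) or a numeric
#'   `steps x n` matrix.
#' @param lag_max Maximum lag in steps (default 10).
#' @param window Step range (records only; default post-burn-in).
#' @return A scalar in `[0, 1]`.  Pairs involving a constant channel are
#'   excluded.
#' @export
zero_lag_synchrony <- function(x, lag_max = 10, window = NULL) {
  X <- as_channel_matrix(x, window)
  R <- lagged_cor(X, lag_max)
  n <- ncol(X)
  up <- upper.tri(R[[1]])
  r0 <- R[[1]][up]
  best_off <- rep(-Inf, sum(up))
  if (lag_max >= 1) {
    for (k in 2:(lag_max + 1)) {
      best_off <- pmax(best_off, R[[k]][up], t(R[[k]])[up])
    }
  }
  ok <- is.finite(r0) & is.finite(best_off)
  if (!any(ok)) stop("degenerate-variance error: no varying channel pairs")
  mean(r0[ok] >= best_off[ok])
}

as_channel_matrix <- function(x, window = NULL) {
  if (inherits(x, "simulation_record")) {
    window <- window %||% post_burn_steps(x)
    x$Q[window, , drop = FALSE]
  } else {
    as.matrix(x)
  }
}

#' Principal-component spatial eigenmode analysis
#'
#' Decomposes a field trajectory into spatial eigenmodes (principal
#' components of the channel covariance), returning for each leading
#' component its loading pattern, time course, explained-variance
#' fraction, a zero-lag synchrony index, and a spatial damping estimate.
#'
#' The component zero-lag index is the fraction of participating
#' channels (loading magnitude above 10% of the component maximum) whose
#' cross-correlation with the component score peaks at lag zero.  Spatial
#' damping is measured as normalized spatial roughness of the loading
#' pattern: the root-mean-square loading difference per unit distance
#' over neighbouring cell pairs, scaled by the root-mean-square loading.
#' A spatially extended synchronous mode has low roughness; a
#' short-range, rapidly attenuated mode has high roughness.
#'
#' @param x A `simulation_record` or a `steps x n` matrix.
#' @param positions Optional `n x 2` coordinates (taken from the record's
#'   geometry when available); required for spatial damping.
#' @param window Step range (records only).
#' @param n_components Number of leading components to characterize.
#' @param lag_max Lag window for the zero-lag index.
#' @return An object of class `eigenmode_set`: `components` (orthonormal
#'   loadings, columns ordered by explained variance), `scores`,
#'   `explained_variance`, `zero_lag_index`, `spatial_damping`.
#' @export
#' @examples
#' s <- sin(seq(0, 20, length.out = 400))
#' em <- eigenmode_decomposition(cbind(s, s, s))
#' em$explained_variance[1]
eigenmode_decomposition <- function(x, positions = NULL, window = NULL,
                                    n_components = 4, lag_max = 10) {
  X <- as_channel_matrix(x, window)
  if (ncol(X) < 2) stop("invalid parameter: need >= 2 channels")
  if (inherits(x, "simulation_record") && is.null(positions))
    positions <- x$geometry$positions
  v <- apply(X, 2, stats::var)
  if (all(v == 0)) stop("degenerate-variance error: constant record")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  comp <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  ev <- pr$sdev^2 / sum(pr$sdev^2)

  zli <- numeric(k)
  damp <- rep(NA_real_, k)
  Xc <- sweep(X, 2, colMeans(X))
  for (c in seq_len(k)) {
    zli[c] <- component_zero_lag(Xc, scores[, c], comp[, c], lag_max)
    if (!is.null(positions)) damp[c] <- loading_roughness(comp[, c], positions)
  }
  structure(list(components = comp, scores = scores,
                 explained_variance = ev[seq_len(k)],
                 explained_variance_all = ev,
                 zero_lag_index = zli, spatial_damping = damp,
                 center = pr$center),
            class = "eigenmode_set")
}

# Fraction of participating channels whose ccf with the component score
# peaks at lag zero.  The channel's own contribution is removed from the
# score (leave-one-out) so a set of unrelated channels scores at chance,
# not 1 through self-correlation; the sign of the loading is applied so
# anti-phase channels of a synchronous mode still count as zero-lag.
component_zero_lag <- function(Xc, score, loading, lag_max) {
  keep <- abs(loading) > 0.1 * max(abs(loading))
  sc0 <- score - mean(score)
  L <- length(sc0)
  hits <- 0L
  tot <- 0L
  for (i in which(keep)) {
    xi <- Xc[, i] * sign(loading[i])
    if (stats::sd(xi) == 0) next
    sc <- sc0 - loading[i] * sign(loading[i]) * xi
    if (stats::sd(sc) == 0) next
    cc <- vapply(-lag_max:lag_max, function(k) {
      if (k >= 0) sum(xi[seq_len(L - k)] * sc[k + seq_len(L - k)]) / (L - k)
      else sum(sc[seq_len(L + k)] * xi[-k + seq_len(L + k)]) / (L + k)
    }, numeric(1))
    tot <- tot + 1L
    if (cc[lag_max + 1] >= max(cc)) hits <- hits + 1L
  }
  if (tot == 0) return(NA_real_)
  hits / tot
}

# Normalized spatial roughness of a loading pattern (see
# eigenmode_decomposition); neighbour radius defaults to 1.5 x median
# nearest-neighbour distance.
loading_roughness <- function(loading, positions, radius = NULL) {
  D <- pair_dist(positions)
  diag(D) <- Inf
  radius <- radius %||% (1.5 * stats::median(apply(D, 1, min)))
  nb <- which(D <= radius & upper.tri(D), arr.ind = TRUE)
  if (nrow(nb) == 0) return(NA_real_)
  dl <- (loading[nb[, 1]] - loading[nb[, 2]]) / D[nb]
  sqrt(mean(dl^2)) / sqrt(mean(loading^2))
}

#' Reconstruct a centered record from an eigenmode set
#'
#' @param em An `eigenmode_set` containing all components.
#' @return The matrix `scores %*% t(components)` (the centered record
#'   when all components are retained).
#' @export
eigenmode_reconstruct <- function(em) {
  em$scores %*% t(em$components)
}
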