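#' Per-cell zero-lag synchrony scores
#'
#' Mean lag-zero correlation of each cell's pulse-rate series with every
#' other cell — the survival statistic for apoptotic selection.
#'
#' @param x A `simulation_record` or `steps x n` matrix.
#' @param window Step range (records only).
#' @return Length-n numeric vector.
#' @export
cell_synchrony_scores <- function(x, window = NULL) {
  X <- as_channel_matrix(x, window)
  R <- stats::cor(X)
  diag(R) <- NA
  rowMeans(R, na.rm = TRUE)
}

#' Apoptotic selection for synchrony
#'
#' Removes the `cull_fraction` of cells with the lowest mean zero-lag
#' correlation to the population, emulating activity-dependent apoptosis
#' that favours synchronously firing neurons.  Geometry and all gain
#' matrices are pruned and renumbered consistently.
#'
#' @param field A `neural_field`.
#' @param synchrony_scores Per-cell scores (e.g.
#'   [cell_synchrony_scores()]); required unless `record` is given.
#' @param cull_fraction Fraction to remove, in `[0, 1)`.
#' @param record Optional `simulation_record` from which scores are
#'   computed.
#' @return The reduced `neural_field`, with attribute `kept` (indices of
#'   survivors in the original numbering).
#' @export
apoptotic_selection <- function(field, synchrony_scores = NULL,
                                cull_fraction = 0.1, record = NULL) {
  stopifnot(inherits(field, "neural_field"))
  if (cull_fraction < 0 || cull_fraction >= 1)
    stop("invalid parameter: cull_fraction must be in [0, 1)")
  if (is.null(synchrony_scores)) {
    if (is.null(record)) stop("invalid parameter: provide scores or a record")
    synchrony_scores <- cell_synchrony_scores(record)
  }
  n <- field$geometry$n
  if (length(synchrony_scores) != n)
    stop("invalid parameter: one synchrony score per cell required")
  n_cull <- floor(cull_fraction * n)
  if (n - n_cull < 2)
    stop("over-cull error: fewer than 2 cells would remain")
  if (n_cull == 0) {
    attr(field, "kept") <- seq_len(n)
    return(field)
  }
  kept <- sort(order(synchrony_scores)[(n_cull + 1):n])
  geo <- field$geometry
  geo$n <- length(kept)
  geo$positions <- geo$positions[kept, , drop = FALSE]
  geo$ei <- geo$ei[kept]
  geo$delay <- geo$delay[kept, kept, drop = FALSE]
  gains <- field$gains
  for (nm in c("eps", "g", "rho", "sign", "mask"))
    gains[[nm]] <- gains[[nm]][kept, kept, drop = FALSE]
  if (!is.null(gains$row_budget)) gains$row_budget <- gains$row_budget[kept]
  if (!is.null(gains$theta_bcm)) gains$theta_bcm <- gains$theta_bcm[kept]
  field$geometry <- geo
  field$gains <- gains
  attr(field, "kept") <- kept
  field
}

#' Distance-decay surrogate synchrony matrix
#'
#' Stand-in pairwise zero-lag correlation for morphogenesis experiments
#' without a field simulation: `exp(-d / l)` with the coupling range `l`
#' the mean of the two cells' axon scales.
#'
#' @param layout A `cell_layout`.
#' @return An n x n correlation-like matrix with unit diagonal.
#' @export
surrogate_synchrony <- function(layout) {
  stopifnot(inherits(layout, "cell_layout"))
  D <- pair_dist(layout$positions)
  lscale <- outer(layout$axon_scale, layout$axon_scale, "+") / 2
  S <- exp(-D / lscale)
  diag(S) <- 1
  S
}

#' Reconstruct symmetric bidirectional connections
#'
#' Connects cell pairs whose zero-lag correlation exceeds a threshold
#' and whose separation is within axonal reach (the sum of the two axon
#' scales) — the monosynaptic couplings expected to emerge through
#' symmetric exchanges as synchrony is maximized.  All edges are
#' unordered and flagged symmetric.  Patch-to-local edges are
#' additionally constrained to arcs radiating from column centers: the
#' bearing of the patch soma and of the local soma from the local cell's
#' cluster center must agree within `arc_tol` degrees.
#'
#' @param layout A `cell_layout`.
#' @param synchrony Pairwise correlation matrix (e.g. `cor` of a record's
#'   pulse rates aligned with the layout, or [surrogate_synchrony()]).
#' @param threshold Minimum zero-lag correlation (default 0.5).
#' @param arc_tol Angular tolerance in degrees for patch-to-local arcs
#'   (default 45).
#' @return An object of class `connection_graph`: data frame `edges`
#'   (`i`, `j`, `weight`, `symmetric`) plus the layout reference.  An
#'   empty result is returned with a warning, not an error.
#' @export
reconstruct_symmetric_connections <- function(layout, synchrony,
                                              threshold = 0.5,
                                              arc_tol = 45) {
  stopifnot(inherits(layout, "cell_layout"))
  n <- nrow(layout$positions)
  if (!is.matrix(synchrony) || any(dim(synchrony) != n))
    stop("invalid parameter: synchrony matrix must align with the layout")
  D <- pair_dist(layout$positions)
  reach <- outer(layout$axon_scale, layout$axon_scale, "+")
  ok <- upper.tri(D) & synchrony > threshold & D <= reach

  # arc constraint for patch-to-local pairs
  centers <- tryCatch(cluster_centers(layout), error = function(e) NULL)
  if (!is.null(centers) && nrow(centers) >= 1) {
    is_local <- layout$population == "local"
    loc_idx <- which(is_local)
    cd <- pair_dist_xy(layout$positions[loc_idx, , drop = FALSE], centers)
    own_center <- centers[apply(cd, 1, which.min), , drop = FALSE]
    center_of <- matrix(NA_real_, n, 2)
    center_of[loc_idx, ] <- own_center
    idx <- which(ok, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      pl <- xor(is_local[i], is_local[j])
      if (!pl) next
      loc <- if (is_local[i]) i else j
      pat <- if (is_local[i]) j else i
      ctr <- center_of[loc, ]
      if (any(is.na(ctr))) next
      b_loc <- atan2(layout$positions[loc, 2] - ctr[2],
                     layout$positions[loc, 1] - ctr[1]) * 180 / pi
      b_pat <- atan2(layout$positions[pat, 2] - ctr[2],
                     layout$positions[pat, 1] - ctr[1]) * 180 / pi
      dang <- abs(((b_loc - b_pat + 180) %% 360) - 180)
      if (dang > arc_tol) ok[i, j] <- FALSE
    }
  }

  idx <- which(ok, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      weight = synchrony[idx], symmetric = TRUE)
  if (nrow(edges) == 0)
    warning("empty graph: no pair passed the correlation and distance rules")
  structure(list(edges = edges, n = n, layout = layout),
            class = "connection_graph")
}

pair_dist_xy <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Adjacency matrix of a connection graph
#'
#' @param graph A `connection_graph`.
#' @return A symmetric n x n weight matrix.
#' @export
graph_adjacency <- function(graph) {
  stopifnot(inherits(graph, "connection_graph"))
  A <- matrix(0, graph$n, graph$n)
  if (nrow(graph$edges)) {
    A[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$weight
    A[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$weight
  }
  A
}
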