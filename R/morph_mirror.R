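#' Reflect points across a line
#'
#' @param pts An `n x 2` position matrix.
#' @param axis A list with `point` (a point on the line) and `normal`
#'   (unit normal of the line).
#' @return The reflected positions.
#' @export
reflect_points <- function(pts, axis) {
  u <- axis$normal / sqrt(sum(axis$normal^2))
  s <- (pts[, 1] - axis$point[1]) * u[1] + (pts[, 2] - axis$point[2]) * u[2]
  pts - 2 * cbind(s * u[1], s * u[2])
}

signed_side <- function(pts, axis) {
  u <- axis$normal / sqrt(sum(axis$normal^2))
  (pts[, 1] - axis$point[1]) * u[1] + (pts[, 2] - axis$point[2]) * u[2]
}

#' Mirror-symmetry score of a layout about an axis
#'
#' Reflects the cells on one side of the candidate axis onto the other
#' and registers them by two-way nearest-neighbour matching (within
#' population when labels are available).  The score is
#' `1 - d_obs / d_null`, where `d_obs` is the mean matched distance and
#' `d_null` its expectation over `n_perm` draws replacing the reflected
#' side with uniform random cells in its bounding region; clipped to
#' `[-1, 1]`.  A layout united with its exact reflection scores 1; an
#' unrelated pair of point sets scores near 0 relative to the
#' permutation null.
#'
#' With `axis = "fit"`, candidate axes through the layout centroid and
#' through midpoints of cluster-center pairs are searched over
#' orientations in 5-degree steps and the best-scoring axis is returned.
#'
#' @param x A `cell_layout`, a `connection_graph` (its layout is used),
#'   or an `n x 2` position matrix.
#' @param axis A list with `point` and `normal`, or `"fit"`.
#' @param n_perm Permutation-null draws (>= 99 recommended).
#' @param band Half-width of the collision band reported as
#'   `blanket_cells`, as a fraction of the layout extent (default 0.05).
#' @param seed Seed for the permutation null.
#' @return An object of class `mirror_pair_report`: `axis`, `score`,
#'   `blanket_cells`, `null_mean`, `null_sd`, `n_left`, `n_right`.
#'   Sides differing by more than 50% in cell count give an
#'   unbalanced-sides warning (the score is still computed).
#' @export
mirror_symmetry_score <- function(x, axis = "fit", n_perm = 99,
                                  band = 0.05, seed = 1) {
  pts <- mirror_points_of(x)
  pop <- mirror_pop_of(x, nrow(pts))
  if (identical(axis, "fit")) {
    axis <- fit_mirror_axis(pts, pop, x)
  }
  score_axis(pts, pop, axis, n_perm = n_perm, band = band, seed = seed)
}

mirror_points_of <- function(x) {
  if (inherits(x, "connection_graph")) x$layout$positions
  else if (inherits(x, "cell_layout")) x$positions
  else as.matrix(x)
}

mirror_pop_of <- function(x, n) {
  if (inherits(x, "connection_graph")) x$layout$population
  else if (inherits(x, "cell_layout")) x$population
  else rep("cell", n)
}

fit_mirror_axis <- function(pts, pop, x) {
  centers <- tryCatch(cluster_centers(if (inherits(x, "cell_layout")) x
                                      else pts),
                      error = function(e) NULL)
  cand_pts <- rbind(colMeans(pts),
                    if (!is.null(centers) && nrow(centers) >= 2) {
                      cp <- utils::combn(nrow(centers), 2)
                      t((centers[cp[1, ], , drop = FALSE] +
                           centers[cp[2, ], , drop = FALSE]) / 2)
                    })
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(nrow(cand_pts))) {
    for (deg in seq(0, 175, by = 5)) {
      a <- list(point = cand_pts[r, ],
                normal = c(cos(deg * pi / 180), sin(deg * pi / 180)))
      sc <- tryCatch(
        score_axis(pts, pop, a, n_perm = 0)$score,
        error = function(e) -Inf)
      if (is.finite(sc) && sc > best_score) {
        best_score <- sc
        best <- a
      }
    }
  }
  if (is.null(best)) stop("invalid parameter: no admissible axis found")
  best
}

score_axis <- function(pts, pop, axis, n_perm = 99, band = 0.05, seed = 1) {
  axis$normal <- axis$normal / sqrt(sum(axis$normal^2))
  s <- signed_side(pts, axis)
  left <- s < 0
  right <- s > 0
  if (sum(left) < 4 || sum(right) < 4)
    stop("invalid parameter: need >= 4 cells on each side of the axis")
  if (abs(sum(left) - sum(right)) > 0.5 * max(sum(left), sum(right)))
    warning("unbalanced-sides: cell counts differ by more than 50%")
  refl <- reflect_points(pts[left, , drop = FALSE], axis)
  targ <- pts[right, , drop = FALSE]
  d_obs <- match_distance(refl, targ, pop[left], pop[right])

  extent <- max(apply(pts, 2, function(z) diff(range(z))))
  blanket <- which(abs(s) < band * extent)

  null_scores <- NULL
  d_null_mean <- NA_real_
  if (n_perm > 0) {
    lo <- apply(targ, 2, min)
    hi <- apply(targ, 2, max)
    d_null <- with_seed(child_seed(seed, 41L), {
      vapply(seq_len(n_perm), function(k) {
        fake <- cbind(stats::runif(nrow(refl), lo[1], hi[1]),
                      stats::runif(nrow(refl), lo[2], hi[2]))
        match_distance(fake, targ, pop[left], pop[right])
      }, numeric(1))
    })
    d_null_mean <- mean(d_null)
    null_scores <- 1 - d_null / d_null_mean
  }
  score <- if (is.finite(d_null_mean) && d_null_mean > 0)
    min(max(1 - d_obs / d_null_mean, -1), 1)
  else if (d_obs == 0) 1 else NA_real_
  structure(list(axis = axis, score = score, d_obs = d_obs,
                 blanket_cells = blanket,
                 null_mean = if (is.null(null_scores)) NA_real_
                             else mean(null_scores),
                 null_sd = if (is.null(null_scores)) NA_real_
                           else stats::sd(null_scores),
                 n_left = sum(left), n_right = sum(right)),
            class = "mirror_pair_report")
}

# Two-way nearest-neighbour matched distance, within population labels.
match_distance <- function(a, b, pop_a, pop_b) {
  tot <- 0
  cnt <- 0L
  for (p in unique(c(pop_a, pop_b))) {
    ai <- a[pop_a == p, , drop = FALSE]
    bi <- b[pop_b == p, , drop = FALSE]
    if (nrow(ai) == 0 || nrow(bi) == 0) next
    D <- pair_dist_xy(ai, bi)
    tot <- tot + sum(apply(D, 1, min)) + sum(apply(D, 2, min))
    cnt <- cnt + nrow(ai) + nrow(bi)
  }
  if (cnt == 0) return(NA_real_)
  tot / cnt
}

#' Mean neighbour-pair mirror score of a tiled cluster array
#'
#' For every adjacent pair of cluster centers (separation within
#' `neighbor_factor` times the median center spacing), scores the mirror
#' symmetry of the two clusters' cells about the pair's perpendicular
#' bisector, and averages.  On a square array of chiral cluster motifs
#' with alternating handedness every neighbour pair can be exactly
#' mirrored; on a hexagonal (triangular) array the odd-cycle adjacency
#' frustrates the alternation, so the mean score is strictly lower —
#' the broken-symmetry signature of hexagonal tiling.
#'
#' @param layout A `cell_layout` whose local cells form clusters.
#' @param neighbor_factor Adjacency radius in units of median center
#'   spacing (default 1.4).
#' @param n_perm Null draws per pair passed to the pair scorer.
#' @return A list: `mean_score`, per-pair data frame `pairs`.
#' @export
neighbor_mirror_census <- function(layout, neighbor_factor = 1.4,
                                   n_perm = 49) {
  centers <- cluster_centers(layout)
  memb <- attr(centers, "membership")
  pts <- local_positions(layout)
  D <- pair_dist(centers)
  diag(D) <- Inf
  spacing <- stats::median(apply(D, 1, min))
  adj <- which(upper.tri(D) & D <= neighbor_factor * spacing, arr.ind = TRUE)
  keep_ids <- as.integer(names(table(memb)[table(memb) >= 2]))
  rows <- list()
  for (r in seq_len(nrow(adj))) {
    a <- adj[r, 1]; b <- adj[r, 2]
    pa <- pts[memb == keep_ids[a], , drop = FALSE]
    pb <- pts[memb == keep_ids[b], , drop = FALSE]
    if (nrow(pa) < 4 || nrow(pb) < 4) next
    mid <- (centers[a, ] + centers[b, ]) / 2
    u <- centers[b, ] - centers[a, ]
    axis <- list(point = mid, normal = u / sqrt(sum(u^2)))
    rep_ <- tryCatch(
      score_axis(rbind(pa, pb), rep("cell", nrow(pa) + nrow(pb)),
                 axis, n_perm = n_perm, seed = r),
      error = function(e) NULL)
    if (is.null(rep_)) next
    rows[[length(rows) + 1L]] <- data.frame(a = a, b = b,
                                            score = rep_$score)
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(a = integer(), b = integer(), score = numeric())
  list(mean_score = mean(pairs$score), pairs = pairs)
}
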