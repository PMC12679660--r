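#' Force-equilibrium morphogenesis of a two-population cell layout
#'
#' Relaxes soma positions of a long-axon ("patch") and a short-axon
#' ("local") population under the trade-off between synchrony
#' maximization and wiring-length minimization, using the unit-dimension
#' analogy between mechanical force and synaptic flow.  Three pairwise
#' forces act:
#' \itemize{
#'   \item synchrony attraction, weight `w_synchrony`: each pair attracts
#'     along the gradient of its synchrony *advantage*
#'     `exp(-d/l)/l - exp(-d/L)/L`, where `l` is the pair's coupling
#'     range (mean of the two axon scales) and `L` the patch scale —
#'     only coupling beyond what the long-range patch background already
#'     provides drives aggregation, so the pull vanishes when all axon
#'     scales are equal and sharpens with the patch/local contrast;
#'   \item wiring cost, weight `w_wiring`: a gentle constant attraction
#'     along every connected pair (separation below the sum of axon
#'     scales), the gradient of total wiring length;
#'   \item soma repulsion (fixed weight): `(r0/d)^2` below a cutoff with
#'     packing radius `r0` proportional to arbor size, preventing
#'     collapse and setting the packing scale.
#' }
#' With synchrony weighting only, local cells condense into clusters
#' surrounded by pools of patch cells; with wiring weighting only the
#' layout stays diffuse; with both, columnarity grows with the ratio of
#' patch to local axon scale.
#'
#' @param n_patch,n_local Cell counts (>= 4 each).
#' @param axon_scale_patch,axon_scale_local Axon length scales (length
#'   units); patch must be >= local.
#' @param w_synchrony,w_wiring Non-negative term weights, not both zero.
#' @param seed Integer seed for the initial placement.
#' @param domain Side length of the bounded square domain (reflecting
#'   walls); default `sqrt(n_patch + n_local)` so mean density is one
#'   cell per unit area.
#' @param max_iter Iteration cap (default 2000).
#' @param tol Convergence threshold on maximum displacement per
#'   iteration (domain units, default 1e-3).
#' @param eta Relaxation step size.
#' @param w_repulsion Repulsion weight (default 1; rarely changed).
#' @return An object of class `cell_layout`: `positions` (n x 2),
#'   `population` (`"patch"`/`"local"`), `axon_scale` per cell,
#'   `tiling_class`, `converged`, `iterations`, `domain`.
#' @export
#' @examples
#' lay <- force_equilibrium_layout(20, 40, 6, 1, w_synchrony = 1,
#'                                 w_wiring = 0, seed = 1, max_iter = 300)
#' table(lay$population)
force_equilibrium_layout <- function(n_patch, n_local,
                                     axon_scale_patch = 6,
                                     axon_scale_local = 1,
                                     w_synchrony = 1, w_wiring = 1,
                                     seed = 1, domain = NULL,
                                     max_iter = 2000, tol = 1e-3,
                                     eta = 0.05, w_repulsion = 1) {
  if (n_patch < 4 || n_local < 4)
    stop("invalid parameter: need at least 4 cells per population")
  if (w_synchrony < 0 || w_wiring < 0 || (w_synchrony == 0 && w_wiring == 0))
    stop("invalid parameter: weights must be >= 0 and not both zero")
  if (axon_scale_patch < axon_scale_local)
    stop("invalid parameter: patch axon scale must be >= local axon scale")
  n <- n_patch + n_local
  domain <- domain %||% sqrt(n)
  pop <- rep(c("patch", "local"), c(n_patch, n_local))
  ax <- ifelse(pop == "patch", axon_scale_patch, axon_scale_local)
  pos <- with_seed(child_seed(seed, 21L),
                   matrix(stats::runif(2 * n, 0, domain), ncol = 2))

  lscale <- outer(ax, ax, "+") / 2        # coupling range per pair
  reach <- outer(ax, ax, "+")             # wiring connection radius
  L <- axon_scale_patch                   # long-range (patch) background
  r_cut <- 3
  # internal force scales: the synchrony pull must overcome soma
  # repulsion at short range for short-axon pairs (clustering
  # instability), while the wiring-length gradient stays a gentle,
  # uniform contraction that repulsion spreads into a diffuse packing
  syn_gain <- 12
  wire_gain <- 0.02
  rep_r0 <- 0.2 * lscale                  # packing radius follows arbor size
  max_step <- 0.2
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    dx <- outer(pos[, 1], pos[, 1], "-")  # dx[i,j] = x_i - x_j
    dy <- outer(pos[, 2], pos[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    diag(d) <- Inf
    # Differential synchrony gradient: only coupling beyond what the
    # long-range patch background already provides drives aggregation.
    # It vanishes when all axon scales are equal (diffuse outcome) and
    # grows with the patch/local scale contrast (columnar outcome).
    f_syn <- -w_synchrony * syn_gain *
      pmax(exp(-d / lscale) / lscale - exp(-d / L) / L, 0)
    f_wire <- -w_wiring * wire_gain * (d < reach)
    f_rep <- w_repulsion * (rep_r0 / pmax(d, 0.05))^2 * (d < r_cut)
    fmag <- (f_syn + f_wire + f_rep) / d  # per unit displacement component
    fx <- rowSums(fmag * dx)
    fy <- rowSums(fmag * dy)
    step_x <- pmin(pmax(eta * fx, -max_step), max_step)
    step_y <- pmin(pmax(eta * fy, -max_step), max_step)
    pos[, 1] <- reflect_wall(pos[, 1] + step_x, domain)
    pos[, 2] <- reflect_wall(pos[, 2] + step_y, domain)
    if (max(abs(c(step_x, step_y))) < tol) {
      converged <- TRUE
      break
    }
  }

  layout <- structure(list(positions = pos, population = pop,
                           axon_scale = ax,
                           axon_scales = c(patch = axon_scale_patch,
                                           local = axon_scale_local),
                           domain = domain, converged = converged,
                           iterations = it, tiling_class = NA_character_),
                      class = "cell_layout")
  layout$tiling_class <- tryCatch(tiling_classification(layout),
                                  error = function(e) "irregular")
  layout
}

reflect_wall <- function(x, L) {
  x <- abs(x)
  over <- x > L
  x[over] <- 2 * L - x[over]
  pmin(pmax(x, 0), L)
}

#' @export
print.cell_layout <- function(x, ...) {
  cat("<cell_layout>", sum(x$population == "patch"), "patch +",
      sum(x$population == "local"), "local cells; tiling:",
      x$tiling_class, "\n")
  invisible(x)
}

local_positions <- function(layout) {
  if (inherits(layout, "cell_layout"))
    layout$positions[layout$population == "local", , drop = FALSE]
  else as.matrix(layout)
}

#' Columnarity index of a layout
#'
#' Clustering statistic of the short-axon somas against complete spatial
#' randomness (CSR): the observed mean nearest-neighbour distance is
#' compared with its Monte-Carlo expectation under CSR at the same
#' intensity inside the points' convex hull, and mapped to
#' `1 - observed / expected`, clipped to `[0, 1]`.  A Poisson-diffuse
#' layout scores near 0; tight, well-separated clusters score near 1.
#' Invariant under rotation and translation.
#'
#' @param layout A `cell_layout` (local cells are used) or an `n x 2`
#'   position matrix.
#' @param n_mc Number of CSR Monte-Carlo draws (default 99).
#' @param seed Seed for the CSR draws.
#' @return A scalar in `[0, 1]`.
#' @export
columnarity_index <- function(layout, n_mc = 99, seed = 1) {
  pts <- local_positions(layout)
  if (nrow(pts) < 8)
    stop("invalid parameter: need >= 8 local cells")
  if (max(pair_dist(pts)) < 1e-12)
    stop("degenerate-layout error: all positions coincident")
  obs <- mean_nn(pts)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  e_csr <- with_seed(child_seed(seed, 31L), {
    mean(vapply(seq_len(n_mc),
                function(k) mean_nn(runif_in_hull(nrow(pts), hull)),
                numeric(1)))
  })
  min(max(1 - obs / e_csr, 0), 1)
}

mean_nn <- function(pts) {
  D <- pair_dist(pts)
  diag(D) <- Inf
  mean(apply(D, 1, min))
}

# Uniform points inside a convex hull (rejection from the bounding box).
runif_in_hull <- function(n, hull) {
  out <- matrix(NA_real_, 0, 2)
  lo <- apply(hull, 2, min)
  hi <- apply(hull, 2, max)
  while (nrow(out) < n) {
    m <- 4 * (n - nrow(out)) + 16
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]))
    keep <- in_convex_hull(cand, hull)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Point-in-convex-polygon test (hull vertices in order from chull).
in_convex_hull <- function(pts, hull) {
  nh <- nrow(hull)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(nh)) {
    a <- hull[k, ]
    b <- hull[if (k == nh) 1L else k + 1L, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
      (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cross <= 1e-9
  }
  inside
}

#' Cluster centers of the short-axon population
#'
#' Single-linkage agglomeration cut at `cut_factor` times the median
#' nearest-neighbour distance; clusters with at least `min_size` members
#' are summarized by their centroid.
#'
#' @param layout A `cell_layout` or position matrix.
#' @param cut_factor Linkage cut in units of the median NN distance.
#' @param min_size Minimum cluster size (default 2).
#' @return A matrix of cluster centroids with attribute `membership`.
#' @export
cluster_centers <- function(layout, cut_factor = 3, min_size = 2) {
  pts <- local_positions(layout)
  D <- pair_dist(pts)
  diag(D) <- Inf
  dnn <- stats::median(apply(D, 1, min))
  hc <- stats::hclust(stats::as.dist(pair_dist(pts)), method = "single")
  memb <- stats::cutree(hc, h = cut_factor * dnn)
  sizes <- table(memb)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  centers <- t(vapply(keep, function(k) colMeans(pts[memb == k, , drop = FALSE]),
                      numeric(2)))
  attr(centers, "membership") <- memb
  centers
}

#' Tiling classification of a clustered layout
#'
#' Classifies the lattice of local-cell cluster centers from the angular
#' histogram of nearest-neighbour bonds: the 4-fold and 6-fold circular
#' concentrations `R4 = |mean(exp(4i * theta))|` and `R6` discriminate
#' square from hexagonal packing; weak concentration in both is
#' `"irregular"`.  Layouts whose columnarity is below `diffuse_below`
#' are `"diffuse"`.
#'
#' @param layout A `cell_layout`, or a matrix of cluster centers (in
#'   which case no columnarity gate is applied).
#' @param diffuse_below Columnarity threshold for the diffuse class.
#' @param concentration_min Minimum circular concentration for a lattice
#'   class (default 0.5).
#' @return One of `"square"`, `"hexagonal"`, `"irregular"`, `"diffuse"`.
#' @export
tiling_classification <- function(layout, diffuse_below = 0.3,
                                  concentration_min = 0.5) {
  if (inherits(layout, "cell_layout")) {
    ci <- tryCatch(columnarity_index(layout), error = function(e) 0)
    if (ci < diffuse_below) return("diffuse")
    centers <- cluster_centers(layout)
  } else {
    centers <- as.matrix(layout)
  }
  if (nrow(centers) < 4)
    stop("insufficient-clusters error: need >= 4 cluster centers")
  D <- pair_dist(centers)
  diag(D) <- Inf
  dnn <- apply(D, 1, min)
  radius <- 1.4 * stats::median(dnn)
  ang <- c()
  for (i in seq_len(nrow(centers))) {
    nb <- which(D[i, ] <= radius)
    ang <- c(ang, atan2(centers[nb, 2] - centers[i, 2],
                        centers[nb, 1] - centers[i, 1]))
  }
  R4 <- Mod(mean(exp(4i * ang)))
  R6 <- Mod(mean(exp(6i * ang)))
  if (max(R4, R6) < concentration_min) return("irregular")
  if (R4 >= R6) "square" else "hexagonal"
}
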