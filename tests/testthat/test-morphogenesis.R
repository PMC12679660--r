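test_that("columnarity index separates diffuse from clustered layouts", {
  set.seed(21)
  unif <- matrix(runif(200, 0, 10), ncol = 2)
  expect_lt(columnarity_index(unif), 0.2)

  ctr <- rbind(c(2, 2), c(8, 2), c(2, 8), c(8, 8))
  clust <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(15, ctr[k, 1], 0.1), rnorm(15, ctr[k, 2], 0.1))))
  expect_gt(columnarity_index(clust), 0.8)

  # geometry invariance: rotation + translation
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- clust %*% Rm + 5
  expect_lt(abs(columnarity_index(clust) - columnarity_index(moved)), 0.05)

  expect_error(columnarity_index(matrix(0, 10, 2)), "degenerate-layout")
  expect_error(columnarity_index(unif[1:5, ]), ">= 8")
})

test_that("tiling classification recognizes square and hexagonal lattices", {
  sq <- make_fixture("square-lattice", jitter = 0)
  hx <- make_fixture("hex-lattice", jitter = 0)
  hxj <- make_fixture("hex-lattice", jitter = 0.05, seed = 3)
  expect_identical(tiling_classification(cluster_centers(sq)), "square")
  expect_identical(tiling_classification(cluster_centers(hx)), "hexagonal")
  expect_identical(tiling_classification(cluster_centers(hxj)), "hexagonal")
  expect_error(tiling_classification(matrix(runif(6), 3, 2)),
               "insufficient-clusters")
  set.seed(2)
  diffuse <- make_fixture("clustered-layout")
  diffuse$positions <- matrix(runif(2 * nrow(diffuse$positions), 0, 12),
                              ncol = 2)
  expect_identical(tiling_classification(diffuse), "diffuse")
})

test_that("force equilibrium reproduces the synchrony/wiring trade-off", {
  syn <- force_equilibrium_layout(30, 90, 6, 1, w_synchrony = 1,
                                  w_wiring = 0, seed = 1, max_iter = 1200)
  expect_gt(columnarity_index(syn), 0.7)
  wir <- force_equilibrium_layout(30, 90, 6, 1, w_synchrony = 0,
                                  w_wiring = 1, seed = 1, max_iter = 1200)
  expect_lt(columnarity_index(wir), 0.2)
  # local clusters surrounded by patch cells
  ctr <- cluster_centers(syn)
  pp <- syn$positions[syn$population == "patch", , drop = FALSE]
  lp <- syn$positions[syn$population == "local", , drop = FALSE]
  dmin <- function(a) apply(sqrt(outer(a[, 1], ctr[, 1], "-")^2 +
                                   outer(a[, 2], ctr[, 2], "-")^2), 1, min)
  expect_gt(median(dmin(pp)), 3 * median(dmin(lp)))
  expect_error(force_equilibrium_layout(2, 90, 6, 1, seed = 1),
               "at least 4")
  expect_error(force_equilibrium_layout(30, 90, 6, 1, 0, 0, seed = 1),
               "not both zero")
})

test_that("apoptotic selection culls the least synchronous cells", {
  f <- build_field(list(n = 10, seed = 6))
  expect_identical(apoptotic_selection(f, runif(10), 0)$geometry$n, 10L)

  # nine coherent channels plus one independent cell
  set.seed(12)
  base <- sin(2 * pi * seq_len(500) / 30)
  X <- sapply(1:10, function(i) base + rnorm(500, 0, 0.3))
  X[, 7] <- rnorm(500)
  scores <- cell_synchrony_scores(X)
  expect_equal(which.min(scores), 7L)
  red <- apoptotic_selection(f, scores, 0.1)
  expect_false(7L %in% attr(red, "kept"))
  expect_equal(red$geometry$n, 9L)
  expect_equal(dim(red$gains$g), c(9L, 9L))

  # survivors are at least as synchronous as the full population
  pre <- mean(cor(X)[upper.tri(diag(10))])
  keep <- attr(red, "kept")
  post <- mean(cor(X[, keep])[upper.tri(diag(9))])
  expect_gte(post, pre)

  expect_error(apoptotic_selection(f, scores, 0.95), "over-cull")
})

test_that("symmetric connection reconstruction obeys correlation and reach rules", {
  lay <- make_fixture("clustered-layout", n_clusters = 3, per_cluster = 10,
                      n_patch = 12, axon_scale_patch = 8, seed = 2)
  S <- surrogate_synchrony(lay)
  g <- reconstruct_symmetric_connections(lay, S, threshold = 0.5)
  expect_true(all(g$edges$symmetric))
  A <- graph_adjacency(g)
  expect_identical(A, t(A))

  is_local <- lay$population == "local"
  # local edges are short-range (within-cluster scale); patch-patch
  # edges span between clusters
  D <- as.matrix(dist(lay$positions))
  ll <- g$edges[is_local[g$edges$i] & is_local[g$edges$j], ]
  if (nrow(ll)) expect_lt(max(D[cbind(ll$i, ll$j)]), 1.5)
  pp <- g$edges[!is_local[g$edges$i] & !is_local[g$edges$j], ]
  expect_gt(nrow(pp), 0)
  expect_gt(max(D[cbind(pp$i, pp$j)]), 2)

  # perfectly correlated pair beyond axonal reach: no edge
  far <- make_fixture("clustered-layout", seed = 4)
  Sfar <- matrix(1, nrow(far$positions), nrow(far$positions))
  gfar <- reconstruct_symmetric_connections(far, Sfar, threshold = 0.99)
  Dfar <- as.matrix(dist(far$positions))
  reach <- outer(far$axon_scale, far$axon_scale, "+")
  if (nrow(gfar$edges))
    expect_true(all(Dfar[cbind(gfar$edges$i, gfar$edges$j)] <=
                      reach[cbind(gfar$edges$i, gfar$edges$j)]))
})

test_that("mirror symmetry scoring: exact reflections, nulls, involution", {
  set.seed(31)
  pts <- matrix(runif(60, 0, 2), ncol = 2)
  axis <- list(point = c(2.5, 0), normal = c(1, 0))
  X <- rbind(pts, reflect_points(pts, axis))
  rep1 <- mirror_symmetry_score(X, axis)
  expect_equal(rep1$score, 1)

  # unrelated point sets score near the permutation null
  left <- cbind(runif(30, 0, 2), runif(30, 0, 4))
  right <- cbind(runif(30, 3, 5), runif(30, 0, 4))
  rep2 <- mirror_symmetry_score(rbind(left, right), axis)
  expect_lt(abs(rep2$score - rep2$null_mean), 2.5 * rep2$null_sd)

  # reflection involution: the mirrored layout scores identically
  rep3 <- mirror_symmetry_score(reflect_points(X, axis), axis)
  expect_equal(rep3$d_obs, rep1$d_obs, tolerance = 1e-9)

  expect_error(mirror_symmetry_score(X[1:6, ], axis), ">= 4")
})

test_that("square mirror arrays beat hexagonal arrays (broken symmetry)", {
  sq <- neighbor_mirror_census(make_fixture("square-mirror-array"))
  hx <- neighbor_mirror_census(make_fixture("hex-mirror-array"))
  expect_gt(sq$mean_score, 0.95)
  expect_gt(sq$mean_score, hx$mean_score)
})
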