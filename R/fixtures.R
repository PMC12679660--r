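#' Deterministic test fixtures
#'
#' Generates the synthetic objects used to exercise each stage of the
#' pipeline without external data.  Every fixture is bit-reproducible
#' from its spec (kind, size parameters, seed).
#'
#' Available kinds:
#' \describe{
#'   \item{`synchronous-pair`}{two identical noisy oscillator channels
#'     (`steps x 2` matrix; zero-lag correlation 1).}
#'   \item{`antiphase-pair`}{two exactly anti-phase channels.}
#'   \item{`coupled-field`}{a small simulated field record
#'     (`n`, `steps`, `amplitude`, `plasticity` parameters).}
#'   \item{`clustered-layout`}{a `cell_layout` with `n_clusters` tight
#'     local-cell clusters and scattered patch cells.}
#'   \item{`square-lattice`, `hex-lattice`}{cluster blobs centered on a
#'     jittered square / hexagonal (triangular) lattice
#'     (`nx`, `ny`, `spacing`, `jitter`, `per_cluster`).}
#'   \item{`square-mirror-array`, `hex-mirror-array`}{lattices of chiral
#'     cluster motifs (4-fold pinwheel / 3-fold triskelion) with
#'     handedness assigned by two-colouring the adjacency — exactly
#'     mirror-paired neighbours on the square lattice, frustrated on the
#'     hexagonal one.}
#'   \item{`rigid-image`}{a `rigid_image_spec` (`moving` switches the
#'     velocity components on).}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param ... Size parameters overriding the kind's defaults.
#' @param seed Integer seed (default 1).
#' @return A module-appropriate object.
#' @export
#' @examples
#' x <- make_fixture("synchronous-pair", steps = 100)
#' cor(x[, 1], x[, 2])   # 1
make_fixture <- function(kind, ..., seed = 1) {
  args <- list(...)
  kinds <- c("synchronous-pair", "antiphase-pair", "coupled-field",
             "clustered-layout", "square-lattice", "hex-lattice",
             "square-mirror-array", "hex-mirror-array", "rigid-image")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "))
  switch(kind,
    "synchronous-pair" = fixture_pair(args, seed, antiphase = FALSE),
    "antiphase-pair" = fixture_pair(args, seed, antiphase = TRUE),
    "coupled-field" = fixture_field(args, seed),
    "clustered-layout" = fixture_clustered(args, seed),
    "square-lattice" = fixture_lattice(args, seed, hex = FALSE,
                                       mirror = FALSE),
    "hex-lattice" = fixture_lattice(args, seed, hex = TRUE, mirror = FALSE),
    "square-mirror-array" = fixture_lattice(args, seed, hex = FALSE,
                                            mirror = TRUE),
    "hex-mirror-array" = fixture_lattice(args, seed, hex = TRUE,
                                         mirror = TRUE),
    "rigid-image" = fixture_image(args, seed))
}

fixture_pair <- function(args, seed, antiphase) {
  steps <- args$steps %||% 1000L
  period <- args$period %||% 40
  noise <- args$noise %||% 0.2
  x <- sin(2 * pi * seq_len(steps) / period) +
    with_seed(child_seed(seed, 51L), stats::rnorm(steps, 0, noise))
  cbind(a = x, b = if (antiphase) -x else x)
}

fixture_field <- function(args, seed) {
  n <- args$n %||% 16L
  steps <- args$steps %||% 1000L
  amplitude <- args$amplitude %||% 0.2
  plast <- args$plasticity %||% list(enabled = TRUE)
  field <- build_field(list(n = n, v = args$v %||% 1,
                            seed = child_seed(seed, 52L)))
  drive <- white_noise_drive(n, steps, amplitude, child_seed(seed, 53L))
  simulate_field(field, steps, drive = drive, plasticity = plast,
                 store_phi = isTRUE(args$store_phi))
}

fixture_clustered <- function(args, seed) {
  n_clusters <- args$n_clusters %||% 4L
  per_cluster <- args$per_cluster %||% 12L
  n_patch <- args$n_patch %||% 20L
  spread <- args$spread %||% 0.3
  domain <- args$domain %||% 12
  with_seed(child_seed(seed, 54L), {
    ctr <- matrix(stats::runif(2 * n_clusters, 0.2 * domain, 0.8 * domain),
                  ncol = 2)
    # enforce separation by resampling close pairs
    for (tries in 1:200) {
      D <- pair_dist(ctr)
      diag(D) <- Inf
      bad <- which(apply(D, 1, min) < 0.3 * domain / sqrt(n_clusters))
      if (!length(bad)) break
      ctr[bad[1], ] <- stats::runif(2, 0.2 * domain, 0.8 * domain)
    }
    loc <- do.call(rbind, lapply(seq_len(n_clusters), function(k) {
      cbind(stats::rnorm(per_cluster, ctr[k, 1], spread),
            stats::rnorm(per_cluster, ctr[k, 2], spread))
    }))
    pat <- matrix(stats::runif(2 * n_patch, 0, domain), ncol = 2)
    new_layout(rbind(pat, loc),
               rep(c("patch", "local"), c(n_patch, nrow(loc))),
               args$axon_scale_patch %||% 6, args$axon_scale_local %||% 1,
               domain)
  })
}

fixture_lattice <- function(args, seed, hex, mirror) {
  nx <- args$nx %||% 4L
  ny <- args$ny %||% 4L
  spacing <- args$spacing %||% 4
  jitter <- args$jitter %||% 0
  per_cluster <- args$per_cluster %||% if (mirror) NULL else 8L
  centers <- list()
  color <- integer(0)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      x <- i * spacing + if (hex && j %% 2 == 0) spacing / 2 else 0
      y <- j * spacing * if (hex) sqrt(3) / 2 else 1
      centers[[length(centers) + 1L]] <- c(x, y)
      # two-colouring: exact on the square grid; greedy (row-wise
      # alternation) on the triangular grid, where odd cycles make a
      # proper colouring impossible.
      color <- c(color, (i + j) %% 2L)
    }
  }
  centers <- do.call(rbind, centers)
  with_seed(child_seed(seed, 55L), {
    centers <- centers + matrix(stats::rnorm(length(centers), 0,
                                             jitter * spacing),
                                ncol = 2)
    pts <- list()
    for (c0 in seq_len(nrow(centers))) {
      blob <- if (mirror) {
        motif <- if (hex) motif_triskelion(0.18 * spacing)
                 else motif_pinwheel(0.18 * spacing)
        # Opposite handedness = reflection across the vertical line, the
        # edge-bisector reflection class closed under the motif's
        # rotational symmetry (C4 on the square grid, C3 on the
        # triangular grid), so every properly coloured neighbour pair is
        # an exact mirror pair.
        if (color[c0] == 1L) cbind(-motif[, 1], motif[, 2]) else motif
      } else {
        cbind(stats::rnorm(per_cluster, 0, 0.05 * spacing),
              stats::rnorm(per_cluster, 0, 0.05 * spacing))
      }
      pts[[c0]] <- sweep(blob, 2, centers[c0, ], "+")
    }
    loc <- do.call(rbind, pts)
    new_layout(loc, rep("local", nrow(loc)),
               args$axon_scale_patch %||% spacing,
               args$axon_scale_local %||% 1,
               max(loc) + spacing)
  })
}

# Chiral 4-fold pinwheel motif (no mirror symmetry, C4 rotation symmetry).
motif_pinwheel <- function(r) {
  a <- c(0, 90, 180, 270) * pi / 180
  b <- (c(0, 90, 180, 270) + 35) * pi / 180
  rbind(cbind(r * cos(a), r * sin(a)),
        cbind(0.55 * r * cos(b), 0.55 * r * sin(b)))
}

# Chiral 3-fold triskelion motif (C3 rotation symmetry).
motif_triskelion <- function(r) {
  a <- c(0, 120, 240) * pi / 180
  b <- (c(0, 120, 240) + 45) * pi / 180
  rbind(cbind(r * cos(a), r * sin(a)),
        cbind(0.55 * r * cos(b), 0.55 * r * sin(b)))
}

new_layout <- function(pos, pop, ax_patch, ax_local, domain) {
  ax <- ifelse(pop == "patch", ax_patch, ax_local)
  structure(list(positions = pos, population = pop, axon_scale = ax,
                 axon_scales = c(patch = ax_patch, local = ax_local),
                 domain = domain, converged = TRUE, iterations = 0L,
                 tiling_class = NA_character_),
            class = "cell_layout")
}

fixture_image <- function(args, seed) {
  moving <- isTRUE(args$moving)
  with_seed(child_seed(seed, 56L), {
    rigid_image_spec(
      scale = args$scale %||% stats::runif(1, 0.5, 2),
      rotation = args$rotation %||% stats::runif(2, 0, 180),
      position = args$position %||% stats::rnorm(3),
      velocity_pose = if (moving) stats::rnorm(3, 0, 0.1) else c(0, 0, 0),
      velocity_position = if (moving) stats::rnorm(3) else c(0, 0, 0))
  })
}
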