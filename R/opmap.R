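#' Atlas of local maps tiling a domain
#'
#' @param maps A list of `local_map` objects.
#' @param overlap Allowed overlap fraction between adjacent map supports
#'   (bookkeeping only; assignment of grid points is nearest-center).
#' @return An object of class `map_atlas`.
#' @export
map_atlas <- function(maps, overlap = 0) {
  if (length(maps) == 0) stop("invalid parameter: atlas must be non-empty")
  if (!all(vapply(maps, inherits, logical(1), "local_map")))
    stop("invalid parameter: all atlas entries must be local_map objects")
  centers <- vapply(maps, function(m) m$p0, complex(1))
  structure(list(maps = maps, centers = centers, overlap = overlap),
            class = "map_atlas")
}

#' Synthesize an orientation-preference map from an atlas
#'
#' Rasterizes orientation preference over a rectangular grid: each grid
#' point is governed by its nearest map center (hard Voronoi boundaries)
#' and takes the orientation implied by that map's angle-halving
#' preimage direction, modulo 180 degrees.  Every local map contributes
#' exactly one pinwheel singularity at its center; boundaries between
#' maps of opposite chirality are mirror seams.
#'
#' @param atlas A `map_atlas` (or a single `local_map`).
#' @param resolution Grid spacing (> 0).
#' @param domain Optional `c(xmin, xmax, ymin, ymax)`; default the
#'   bounding box of the map centers expanded by the median center
#'   spacing (or by `3 * k` for a single map).
#' @param blend `"nearest"` (default): hard Voronoi assignment, exact
#'   per-map fields with orientation seams at boundaries.  `"soft"`:
#'   distance-weighted vector averaging in doubled-angle space, giving
#'   a smooth field in which boundary features (saddle points of the
#'   orientation phase) exist.
#' @param classify Also run [classify_op_features()] (default TRUE).
#' @return An object of class `op_map`: `raster` (matrix of orientations
#'   in degrees, rows = y, columns = x), `xs`, `ys`, `assignment` (map
#'   index per grid point), `features`.
#' @export
synthesize_op_map <- function(atlas, resolution, domain = NULL,
                              blend = c("nearest", "soft"),
                              classify = TRUE) {
  if (inherits(atlas, "local_map")) atlas <- map_atlas(list(atlas))
  stopifnot(inherits(atlas, "map_atlas"))
  blend <- match.arg(blend)
  if (!is.finite(resolution) || resolution <= 0)
    stop("invalid parameter: resolution must be > 0")
  ctr <- atlas$centers
  if (is.null(domain)) {
    if (length(ctr) > 1) {
      D <- pair_dist(cbind(Re(ctr), Im(ctr)))
      diag(D) <- Inf
      pad <- stats::median(apply(D, 1, min))
    } else {
      pad <- 3 * atlas$maps[[1]]$k
    }
    domain <- c(min(Re(ctr)) - pad, max(Re(ctr)) + pad,
                min(Im(ctr)) - pad, max(Im(ctr)) + pad)
  }
  if (length(ctr) > 1) {
    D <- pair_dist(cbind(Re(ctr), Im(ctr)))
    diag(D) <- Inf
    if (resolution > min(D) / 2)
      warning("undersampling: resolution coarser than half the ",
              "inter-center spacing")
  }
  # pixel-center grid: map centers then lie generically inside
  # plaquettes, where winding is well defined
  xs <- seq(domain[1] + resolution / 2, domain[2], by = resolution)
  ys <- seq(domain[3] + resolution / 2, domain[4], by = resolution)
  gz <- outer(1i * ys, xs, "+")          # rows y, cols x
  dist_to <- vapply(ctr, function(c0) as.vector(Mod(gz - c0)),
                    numeric(length(gz)))
  assign_idx <- max.col(-matrix(dist_to, ncol = length(ctr)),
                        ties.method = "first")
  raster <- matrix(NA_real_, length(ys), length(xs))
  if (blend == "nearest") {
    for (m in seq_along(atlas$maps)) {
      sel <- assign_idx == m
      if (!any(sel)) next
      z <- gz[sel]
      mp <- atlas$maps[[m]]
      at_ctr <- Mod(z - mp$p0) == 0
      v <- numeric(length(z))
      v[!at_ctr] <- op_at(z[!at_ctr], mp)
      v[at_ctr] <- 0          # singular center: orientation undefined
      raster[sel] <- v
    }
  } else {
    # doubled-angle vector average, Gaussian distance weights with
    # scale half the nearest inter-center spacing
    s <- if (length(ctr) > 1) {
      D <- pair_dist(cbind(Re(ctr), Im(ctr)))
      diag(D) <- Inf
      min(D) / 2
    } else 3 * atlas$maps[[1]]$k
    acc <- complex(length.out = length(gz))
    for (m in seq_along(atlas$maps)) {
      mp <- atlas$maps[[m]]
      z <- as.vector(gz)
      at_ctr <- Mod(z - mp$p0) == 0
      v <- numeric(length(z))
      v[!at_ctr] <- op_at(z[!at_ctr], mp)
      w <- exp(-(Mod(z - mp$p0) / s)^2)
      w[at_ctr] <- 0
      acc <- acc + w * exp(2i * v * pi / 180)
    }
    raster[] <- wrap180(Arg(acc) / 2 * 180 / pi)
  }
  out <- structure(list(raster = raster, xs = xs, ys = ys,
                        assignment = matrix(assign_idx, length(ys),
                                            length(xs)),
                        resolution = resolution, atlas = atlas,
                        features = NULL),
                   class = "op_map")
  if (classify) out$features <- classify_op_features(out)
  out
}

#' Classify features of an orientation-preference raster
#'
#' Detects the three canonical map features:
#' \itemize{
#'   \item singularities (pinwheels): grid plaquettes around which the
#'     orientation winds by a half turn; winding number `+1/2` or `-1/2`
#'     from the sum of wrapped orientation increments;
#'   \item linear zones: connected regions whose orientation gradient
#'     magnitude is below the `linear_quantile` percentile;
#'   \item saddle points: interior low-gradient points at which the
#'     locally unwrapped orientation field has an indefinite Hessian.
#' }
#'
#' @param opmap An `op_map`.
#' @param linear_quantile Gradient percentile bounding linear zones
#'   (default 0.10).
#' @param saddle_quantile Gradient percentile below which a point may be
#'   a saddle (default 0.05).
#' @return A data frame with columns `type`
#'   (`"singularity"`/`"linear_zone"`/`"saddle"`), `x`, `y`, and
#'   `winding` (singularities only, else `NA`).
#' @export
classify_op_features <- function(opmap, linear_quantile = 0.10,
                                 saddle_quantile = 0.05) {
  stopifnot(inherits(opmap, "op_map"))
  R <- opmap$raster
  ny <- nrow(R); nx <- ncol(R)
  feats <- list()

  # --- singularities: plaquette winding of the orientation field, in
  # half turns (a pinwheel winds the 180-degree orientation circle once
  # per physical circuit: winding +-1/2).  Winding is well defined only
  # where the field is continuous, so plaquettes straddling two maps
  # (hard assignment seams) are excluded; near-duplicate detections
  # around one core are merged.
  if (ny >= 2 && nx >= 2) {
    a <- R[-ny, -nx]; b <- R[-ny, -1]; c <- R[-1, -1]; d <- R[-1, -nx]
    wind <- (op_diff(b, a) + op_diff(c, b) + op_diff(d, c) +
               op_diff(a, d)) / 360
    if (!is.null(opmap$assignment)) {
      A <- opmap$assignment
      same <- A[-ny, -nx] == A[-ny, -1] & A[-ny, -1] == A[-1, -1] &
        A[-1, -1] == A[-1, -nx]
      wind[!same] <- 0
    }
    hit <- which(abs(wind) > 0.24, arr.ind = TRUE)
    if (nrow(hit)) {
      sing <- data.frame(
        type = "singularity",
        x = (opmap$xs[hit[, 2]] + opmap$xs[hit[, 2] + 1]) / 2,
        y = (opmap$ys[hit[, 1]] + opmap$ys[hit[, 1] + 1]) / 2,
        winding = sign(wind[hit]) * 0.5)
      feats[[length(feats) + 1L]] <- merge_close_features(
        sing, 1.5 * opmap$resolution)
    }
  }

  # --- gradient magnitude (wrap-aware central differences)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  if (nx >= 3) gx[, 2:(nx - 1)] <-
      op_diff(R[, 3:nx], R[, 1:(nx - 2)]) / (2 * opmap$resolution)
  if (ny >= 3) gy[2:(ny - 1), ] <-
      op_diff(R[3:ny, ], R[1:(ny - 2), ]) / (2 * opmap$resolution)
  gmag <- sqrt(gx^2 + gy^2)
  interior <- matrix(FALSE, ny, nx)
  if (ny > 4 && nx > 4) interior[3:(ny - 2), 3:(nx - 2)] <- TRUE

  # keep singular plaquettes out of the low-gradient classes
  near_sing <- matrix(FALSE, ny, nx)
  sing <- if (length(feats)) feats[[1]] else NULL
  if (!is.null(sing) && nrow(sing)) {
    for (r in seq_len(nrow(sing))) {
      di <- abs(opmap$ys - sing$y[r])
      dj <- abs(opmap$xs - sing$x[r])
      near_sing[di <= 3 * opmap$resolution, dj <= 3 * opmap$resolution] <- TRUE
    }
  }

  thr_lin <- stats::quantile(gmag[interior & !near_sing], linear_quantile,
                             na.rm = TRUE)
  lin <- interior & !near_sing & gmag <= thr_lin
  if (any(lin)) {
    comps <- label_components(lin)
    for (id in setdiff(unique(as.vector(comps)), 0L)) {
      cells <- which(comps == id, arr.ind = TRUE)
      feats[[length(feats) + 1L]] <- data.frame(
        type = "linear_zone",
        x = mean(opmap$xs[cells[, 2]]),
        y = mean(opmap$ys[cells[, 1]]),
        winding = NA_real_)
    }
  }

  # --- saddles: critical points of the orientation phase — strict
  # local minima of the gradient magnitude (the field's gradient
  # vanishes there, typically where mirror-reversal seams cross), away
  # from singularities, with an indefinite local Hessian
  med_g <- stats::median(gmag[interior & !near_sing], na.rm = TRUE)
  sad <- list()
  cand <- which(interior & !near_sing, arr.ind = TRUE)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (gmag[i, j] > saddle_quantile * med_g * 10) next
    nb <- gmag[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (gmag[i, j] > min(nb[-5])) next          # strict local minimum
    c0 <- R[i, j]
    u <- function(ii, jj) op_diff(R[ii, jj], c0)   # unwrap about center
    hxx <- u(i, j + 1) + u(i, j - 1)
    hyy <- u(i + 1, j) + u(i - 1, j)
    hxy <- (u(i + 1, j + 1) + u(i - 1, j - 1) -
              u(i + 1, j - 1) - u(i - 1, j + 1)) / 4
    if (hxx * hyy - hxy^2 < -1e-9)
      sad[[length(sad) + 1L]] <- data.frame(
        type = "saddle", x = opmap$xs[j], y = opmap$ys[i],
        winding = NA_real_)
  }
  if (length(sad))
    feats <- c(feats, list(merge_close_features(do.call(rbind, sad),
                                                3 * opmap$resolution)))

  if (!length(feats))
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      winding = numeric()))
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

# Merge features closer than `radius` into their centroid (keeps the
# first row's type and winding).
merge_close_features <- function(df, radius) {
  if (nrow(df) <= 1) return(df)
  keep <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    if (!keep[r]) next
    d <- sqrt((df$x - df$x[r])^2 + (df$y - df$y[r])^2)
    grp <- which(keep & d <= radius)
    if (length(grp) > 1) {
      df$x[r] <- mean(df$x[grp])
      df$y[r] <- mean(df$y[grp])
      keep[setdiff(grp, r)] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

# 4-connected component labelling of a logical matrix (iterative BFS).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nid <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    nid <- nid + 1L
    queue <- todo[1]
    lab[queue] <- nid
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      i <- (cur - 1L) %% nrow(mask) + 1L
      j <- (cur - 1L) %/% nrow(mask) + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1 || nb[1] > nrow(mask) || nb[2] < 1 || nb[2] > ncol(mask))
          next
        idx <- (nb[2] - 1L) * nrow(mask) + nb[1]
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- nid
          queue <- c(queue, idx)
        }
      }
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Export an OP raster as CSV
#'
#' @param opmap An `op_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_opmap_csv <- function(opmap, path) {
  grid <- expand.grid(x = opmap$xs, y = opmap$ys)
  grid$op_deg <- as.vector(t(opmap$raster))
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Export an OP raster as an 8-bit grayscale PGM image
#'
#' Orientations 0-180 degrees are scaled to gray levels 0-255 and
#' written in the plain-text (P2) PGM format.
#'
#' @param opmap An `op_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_opmap_pgm <- function(opmap, path) {
  g <- round(opmap$raster / 180 * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  utils::write.table(g[rev(seq_len(nrow(g))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
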