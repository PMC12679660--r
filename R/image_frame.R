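#' A global activity pattern
#'
#' Activity samples at the patch-network (global) scale: complex
#' positions, sample times, and activity values.
#'
#' @param P Complex positions.
#' @param t Sample times (scalar or per-sample).
#' @param O Activity values (default 1).
#' @return An object of class `global_pattern`.
#' @export
global_pattern <- function(P, t = 0, O = 1) {
  P <- as.complex(P)
  n <- length(P)
  t <- rep_len(t, n)
  O <- rep_len(O, n)
  if (any(!is.finite(c(Re(P), Im(P), t))))
    stop("invalid parameter: non-finite pattern samples")
  structure(list(P = P, t = t, O = O), class = "global_pattern")
}

#' Disperse a global pattern across an atlas of local maps
#'
#' Projects every pattern sample into every local map whose support
#' covers it: position via the angle-doubling map, time shifted by the
#' metric conduction delay `|P - p| / v` between the global point and
#' its local image.  Sample count is conserved per covering map.
#'
#' @param pattern A `global_pattern`.
#' @param atlas A `map_atlas` (or single `local_map`).
#' @param v Conduction speed (> 0), or `Inf` for delay-free projection.
#' @return A list of `local_image` objects (one per covering map), each
#'   a data frame with columns `p` (complex local position), `t`
#'   (delay-shifted time), `delay`, `value`, plus attribute `map_index`.
#'   An empty list with a warning if no map covers the pattern.
#' @export
#' @examples
#' img <- project_image(global_pattern(1 + 0i), map_atlas(list(local_map())),
#'                      v = Inf)
#' img[[1]]$p
project_image <- function(pattern, atlas, v = Inf) {
  stopifnot(inherits(pattern, "global_pattern"))
  if (inherits(atlas, "local_map")) atlas <- map_atlas(list(atlas))
  stopifnot(inherits(atlas, "map_atlas"))
  if (!(is.infinite(v) || (is.finite(v) && v > 0)))
    stop("invalid parameter: conduction speed must be > 0 or Inf")
  out <- list()
  for (m in seq_along(atlas$maps)) {
    mp <- atlas$maps[[m]]
    covered <- Mod(pattern$P - mp$p0) <= mp$support
    if (!any(covered)) next
    P <- pattern$P[covered]
    p <- global_to_local(P, mp, center_policy = "collapse")
    delay <- if (is.infinite(v)) rep(0, length(P)) else Mod(P - p) / v
    li <- data.frame(p = p, t = pattern$t[covered] - delay,
                     delay = delay, value = pattern$O[covered])
    attr(li, "map_index") <- m
    class(li) <- c("local_image", class(li))
    out[[length(out) + 1L]] <- li
  }
  if (!length(out))
    warning("empty-projection: pattern lies outside all map supports")
  out
}

#' Specification of a rigid moving test image
#'
#' A rigid object in time-varying 3-D space is fixed by an object
#' scale/rotation frame of three coordinates (log scale and two rotation
#' angles), a position frame of three coordinates, and — for a moving
#' image — the translation (velocity) components within both frames.
#'
#' @param scale Object scale (> 0).
#' @param rotation Two rotation angles (degrees).
#' @param position 3-D position.
#' @param velocity_pose Rates of change of `(log scale, rotation)`;
#'   default zeros (static).
#' @param velocity_position 3-D translational velocity; default zeros.
#' @param rigid Must be `TRUE`; non-rigid specs are unsupported.
#' @return An object of class `rigid_image_spec`.
#' @export
rigid_image_spec <- function(scale = 1, rotation = c(0, 0),
                             position = c(0, 0, 0),
                             velocity_pose = c(0, 0, 0),
                             velocity_position = c(0, 0, 0),
                             rigid = TRUE) {
  if (!isTRUE(rigid))
    stop("unsupported-image error: only rigid images have a fixed-size frame")
  stopifnot(length(rotation) == 2, length(position) == 3,
            length(velocity_pose) == 3, length(velocity_position) == 3)
  vals <- c(scale, rotation, position, velocity_pose, velocity_position)
  if (any(!is.finite(vals)))
    stop("invalid parameter: image spec must be finite")
  if (scale <= 0) stop("invalid parameter: scale must be > 0")
  structure(list(scale = scale, rotation = rotation, position = position,
                 velocity_pose = velocity_pose,
                 velocity_position = velocity_position, rigid = TRUE),
            class = "rigid_image_spec")
}

#' Twelve-point representation frame of a rigid moving image
#'
#' Packs a rigid moving image into the fixed twelve-coordinate frame
#' required for static synaptic storage of a spatiotemporal image:
#' three object scale/rotation coordinates, three position coordinates,
#' and the translation (velocity) components within both frames (three
#' each).  The packing order is
#' `(log_scale, rot1, rot2, pos_x, pos_y, pos_z,
#'   d_log_scale, d_rot1, d_rot2, vel_x, vel_y, vel_z)`.
#' A static image has all six translation components exactly zero.  The
#' frame is reconstructible: [frame_to_image_spec()] inverts it.
#'
#' @param image A `rigid_image_spec`.
#' @param image_id Optional identifier.
#' @return An object of class `representation_frame` with the named
#'   length-12 numeric vector `points`.
#' @export
#' @examples
#' fr <- build_representation_frame(rigid_image_spec())
#' length(fr$points)   # 12
build_representation_frame <- function(image, image_id = NULL) {
  stopifnot(inherits(image, "rigid_image_spec"))
  points <- c(log_scale = log(image$scale),
              rot1 = image$rotation[1], rot2 = image$rotation[2],
              pos_x = image$position[1], pos_y = image$position[2],
              pos_z = image$position[3],
              d_log_scale = image$velocity_pose[1],
              d_rot1 = image$velocity_pose[2],
              d_rot2 = image$velocity_pose[3],
              vel_x = image$velocity_position[1],
              vel_y = image$velocity_position[2],
              vel_z = image$velocity_position[3])
  structure(list(points = points, image_id = image_id),
            class = "representation_frame")
}

#' Reconstruct a rigid image spec from its representation frame
#'
#' @param frame A `representation_frame`.
#' @return The `rigid_image_spec` encoded by the frame.
#' @export
frame_to_image_spec <- function(frame) {
  stopifnot(inherits(frame, "representation_frame"))
  p <- frame$points
  if (length(p) != 12)
    stop("invalid parameter: a representation frame has exactly 12 points")
  rigid_image_spec(scale = exp(p[["log_scale"]]),
                   rotation = c(p[["rot1"]], p[["rot2"]]),
                   position = c(p[["pos_x"]], p[["pos_y"]], p[["pos_z"]]),
                   velocity_pose = c(p[["d_log_scale"]], p[["d_rot1"]],
                                     p[["d_rot2"]]),
                   velocity_position = c(p[["vel_x"]], p[["vel_y"]],
                                         p[["vel_z"]]))
}
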