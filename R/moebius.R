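#' Local angle-doubling map of a cortical column
#'
#' The conformal global-to-local projection attached to one short-axon
#' column: displacements from the global (patch-network) scale are
#' scaled by `1/k`, their argument is doubled, and the result is rotated
#' by 90 degrees (the imaginary-unit factor).  `chirality = +1` is the
#' direct (conformal) map; `chirality = -1` is its mirror image — the
#' complex-conjugate (anti-conformal) branch — so that the two
#' handednesses generate mirror-reversed orientation maps with opposite
#' pinwheel winding.
#'
#' @param p0 Column center as a complex number.
#' @param k Scale constant (> 0): global distances map to `1/k` times
#'   themselves.
#' @param chirality `+1` or `-1`.
#' @param support Reach of the map from `p0` at the global scale
#'   (default `Inf`).
#' @return An object of class `local_map`.
#' @export
#' @examples
#' m <- local_map(0 + 0i, k = 2, chirality = 1)
#' global_to_local(1 + 0i, m)   # 0 + 0.5i
local_map <- function(p0 = 0 + 0i, k = 1, chirality = 1L, support = Inf) {
  if (!is.finite(k) || k <= 0) stop("invalid parameter: k must be > 0")
  if (!chirality %in% c(-1, 1))
    stop("invalid parameter: chirality must be +1 or -1")
  structure(list(p0 = as.complex(p0), k = k,
                 chirality = as.integer(chirality), support = support),
            class = "local_map")
}

#' Project a global position into a local map
#'
#' Applies the angle-doubling projection: the local displacement has
#' modulus `|P - p0| / k` and argument `2 * arg(P - p0) + 90` degrees
#' for positive chirality (the mirror-conjugate for negative chirality).
#'
#' @param P Complex global position(s).
#' @param map A `local_map`.
#' @param center_policy What to do at `P = p0`, where the projection is
#'   singular: `"error"` (default) or `"collapse"` (maps to `p0`).
#' @return Complex local position(s).
#' @export
global_to_local <- function(P, map, center_policy = c("error", "collapse")) {
  stopifnot(inherits(map, "local_map"))
  center_policy <- match.arg(center_policy)
  z <- as.complex(P) - map$p0
  at_center <- Mod(z) == 0
  if (any(at_center) && center_policy == "error")
    stop("singular-center error: P = p0 has no defined projection")
  w <- complex(length.out = length(z))
  zz <- z[!at_center]
  ww <- (1i / map$k) * zz^2 / Mod(zz)
  if (map$chirality < 0) ww <- Conj(ww)
  w[!at_center] <- ww
  w[at_center] <- 0
  map$p0 + w
}

#' Invert a local map back to the global scale
#'
#' Inverts the angle-doubling on a chosen branch: the two preimages of a
#' local position differ by 180 degrees in global angle.  The round trip
#' `global_to_local` then `local_to_global` on the matching branch is
#' the identity to machine precision (the maps are invertible 1:1).
#'
#' @param p Complex local position(s).
#' @param map A `local_map`.
#' @param branch `"+"` (principal, default) or `"-"` (the antipodal
#'   preimage).
#' @return Complex global position(s).
#' @export
local_to_global <- function(p, map, branch = c("+", "-")) {
  stopifnot(inherits(map, "local_map"))
  branch <- match.arg(branch)
  w <- as.complex(p) - map$p0
  if (any(Mod(w) == 0))
    stop("singular-center error: p = p0 is the branch point")
  if (map$chirality < 0) w <- Conj(w)
  # w = (i/k) |z| e^{2 i theta}  =>  theta = (Arg(-i k w)) / 2 (+ pi)
  theta <- Arg(-1i * w) / 2 + if (branch == "-") pi else 0
  map$p0 + map$k * Mod(w) * exp(1i * theta)
}

#' Orientation preference induced by a local map
#'
#' The orientation preference at a local position is the direction of
#' its global preimage, taken modulo 180 degrees: as a point makes one
#' full physical circuit around the column center, the preference sweeps
#' exactly one orientation period (the half-twist of the column's
#' Moebius-like configuration).
#'
#' @param p Complex local position(s) (not equal to `p0`).
#' @param map A `local_map`.
#' @return Orientation(s) in degrees, in `[0, 180)`.
#' @export
op_at <- function(p, map) {
  P <- local_to_global(p, map, branch = "+")
  wrap180(Arg(P - map$p0) * 180 / pi)
}

#' Orientation-preference traversal around a closed circuit
#'
#' Evaluates the orientation preference on a circle of radius `radius`
#' around the map center at `step_deg` increments of physical angle,
#' and accumulates the wrapped orientation increments over the closed
#' circuit.  The magnitude of the total traversal is the orientation
#' span covered in one circuit (180 degrees for an angle-doubling map);
#' its sign follows the map's chirality.
#'
#' @param map A `local_map`.
#' @param radius Circuit radius (> 0), local units.
#' @param step_deg Angular step in degrees (default 1).
#' @return A list: `span` (absolute traversal, degrees), `signed_span`,
#'   `op` (the sampled orientations).
#' @export
#' @examples
#' op_circuit_span(local_map())$span   # 180
op_circuit_span <- function(map, radius = 1, step_deg = 1) {
  stopifnot(inherits(map, "local_map"), radius > 0, step_deg > 0)
  ang <- seq(0, 360, by = step_deg) * pi / 180
  p <- map$p0 + radius * exp(1i * ang)
  op <- op_at(p, map)
  dels <- op_diff(op[-1], op[-length(op)])
  total <- sum(dels)
  list(span = abs(total), signed_span = total, op = op[-length(op)])
}
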