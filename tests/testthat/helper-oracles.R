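# Independent oracles used across tests.  These are deliberately naive
# reimplementations (brute force / direct formulas), kept separate from
# the package's computation paths.

# Histogram (plug-in) mutual-information estimate in bits, on
# equal-probability rank bins: invariant to monotone marginal
# transforms, so it estimates the copula MI directly.
hist_mi <- function(x, y, bins = 64) {
  bx <- cut(rank(x, ties.method = "first"), bins, labels = FALSE)
  by <- cut(rank(y, ties.method = "first"), bins, labels = FALSE)
  p <- table(bx, by) / length(x)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

# Hand-unrolled linear field recursion: V(t) = sum_k kw[k+1] *
# (W %*% Qlin(t - k - lag_matrix) + drive(t - k)); Qlin = q0 + slope * V
# (tangent activation).  Used as the small-signal oracle.
linear_field_oracle <- function(W, lag, kw, slope, q0, drive) {
  steps <- nrow(drive)
  n <- ncol(drive)
  sup <- length(kw) - 1L
  pad <- max(lag) + sup
  Q <- matrix(q0, pad + steps, n)
  V <- matrix(0, steps, n)
  S <- matrix(0, pad + steps, n)
  S[seq_len(pad), ] <- rowSums(W)[col(S[seq_len(pad), , drop = FALSE])] * q0
  # history pad: flux from baseline rate q0 (the simulator pads Q with
  # zeros, so pad flux with zeros to match)
  S[seq_len(pad), ] <- 0
  Q[seq_len(pad), ] <- 0
  for (t in seq_len(steps)) {
    r <- pad + t
    Qd <- matrix(Q[cbind(as.vector(r - lag),
                         rep(seq_len(n), each = n))], n, n)
    S[r, ] <- rowSums(W * Qd) + drive[t, ]
    V[t, ] <- as.vector(kw %*% S[r - (0:sup), , drop = FALSE])
    Q[r, ] <- q0 + slope * V[t, ]
  }
  list(V = V, Q = Q[-seq_len(pad), , drop = FALSE])
}

# Minimal synthetic record carrying a prescribed pairwise flux exchange
# (n = 2), for exercising the flux statistics directly.
make_flux_record <- function(phi12, phi21) {
  steps <- length(phi12)
  Phi <- array(0, c(2, 2, steps))
  Phi[1, 2, ] <- phi12
  Phi[2, 1, ] <- phi21
  mask <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  structure(list(
    Q = matrix(0.5, steps, 2), V = matrix(0, steps, 2),
    Se = matrix(0, steps, 2), Si = matrix(0, steps, 2),
    drive = NULL,
    geometry = structure(list(n = 2L,
                              positions = rbind(c(0, 0), c(1, 0)),
                              ei = c("E", "E"), v = 1, dt = 1,
                              delay = matrix(0L, 2, 2),
                              single_population = TRUE),
                         class = "field_geometry"),
    config = list(), burn_in = 0L,
    W_history = list(list(step = 0L, W = matrix(0, 2, 2))),
    balance = data.frame(),
    gains_init = structure(list(mask = mask), class = "gain_state"),
    gains_final = NULL, Phi = Phi, version = "cortigen-record-1"
  ), class = "simulation_record")
}

# Small default field used by several tests.
small_field <- function(seed = 1, n = 16) {
  build_field(list(n = n, seed = seed))
}
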