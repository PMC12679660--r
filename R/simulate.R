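#' Initialize a field state with zero-padded history
#'
#' Creates the history buffers needed before stepping a field: pulse-rate
#' and afferent-flux histories are zero-padded for the warm-up span
#' (maximum conduction lag plus dendritic kernel support), the stated
#' policy for missing history.
#'
#' @param field A `neural_field` from [build_field()].
#' @param kernel A `dendritic_kernel`.
#' @param activation An `activation_function`.
#' @return A list of class `field_state` with history matrices `Qh`
#'   (pulse rates) and `Sh` (aggregate afferent flux plus drive), and the
#'   step counter `t = 0`.
#' @export
field_state <- function(field, kernel, activation) {
  stopifnot(inherits(field, "neural_field"))
  n <- field$geometry$n
  lag <- pmax(field$geometry$delay, 1L)
  pad <- max(lag) + kernel$support
  structure(list(
    Qh = matrix(0, pad, n), Sh = matrix(0, pad, n),
    t = 0L, pad = pad, lag = lag,
    kernel = kernel, activation = activation
  ), class = "field_state")
}

#' Advance a neural field by one time step
#'
#' Applies one update of the field equations: presynaptic flux is the
#' signed product of the three gains with the conduction-delayed
#' presynaptic pulse rate; the dendritic potential is the kernel
#' convolution of aggregate afferent flux plus external drive; the pulse
#' rate is the sigmoid of the potential.  Delayed terms older than the
#' available history are taken as zero (the zero-padding warm-up policy);
#' a state built by [field_state()] always carries enough padding, and a
#' hand-built state with insufficient history raises a warm-up error.
#'
#' @param state A `field_state`.
#' @param field The `neural_field` (geometry and gains).
#' @param drive_t External drive vector at this step (flux units),
#'   default zeros.
#' @return The updated `field_state`, with the newly computed `phi`
#'   (n x n presynaptic flux matrix), `V` and `Q` vectors attached.
#' @export
#' @examples
#' f <- build_field(list(n = 4, v = 1, seed = 1))
#' st <- field_state(f, dendritic_kernel(2), activation_function())
#' st <- field_step(st, f)
#' range(st$Q)
field_step <- function(state, field, drive_t = NULL) {
  stopifnot(inherits(state, "field_state"))
  n <- field$geometry$n
  if (nrow(state$Qh) < max(state$lag) + state$kernel$support)
    stop("warm-up error: history shorter than max delay + kernel support; ",
         "zero-pad the history buffers (see field_state)")
  drive_t <- drive_t %||% numeric(n)
  W <- gain_matrix(field$gains)
  r <- nrow(state$Qh)
  Qd <- matrix(state$Qh[cbind(as.vector(r + 1L - state$lag),
                              rep(seq_len(n), each = n))], n, n)
  phi <- W * Qd
  s <- rowSums(phi) + drive_t
  Sh <- rbind(state$Sh, s)
  kw <- state$kernel$weights
  sup <- state$kernel$support
  V <- as.vector(kw %*% Sh[nrow(Sh) - (0:sup), , drop = FALSE])
  Q <- apply_activation(state$activation, V)
  state$Qh <- rbind(state$Qh, Q)
  state$Sh <- Sh
  state$t <- state$t + 1L
  state$phi <- phi
  state$V <- V
  state$Q <- Q
  state
}

# Effective signed connection weight: sign * eps * g * rho, zero off the
# structural mask.  Any zero gain silences the synapse.
gain_matrix <- function(gains) {
  gains$sign * gains$eps * gains$g * gains$rho * gains$mask
}

#' Simulate a neural field
#'
#' Runs the full discrete-time loop: delayed flux exchange, dendritic
#' convolution, sigmoid pulse generation, with Hebbian gain growth and
#' anti-Hebbian excitatory/inhibitory normalization interleaved at a
#' configured period.  The run is bit-reproducible given the field
#' configuration, drive and seed.
#'
#' @param field A `neural_field` from [build_field()].
#' @param steps Number of time steps (>= 0).
#' @param drive A `steps x n` drive matrix (e.g. [white_noise_drive()]),
#'   or `NULL` for no external input.
#' @param kernel,activation Dendritic kernel and activation function;
#'   defaults `dendritic_kernel(2)` and `activation_function(0, 1, 1)`.
#' @param plasticity A list: `enabled`, `period` (steps between plasticity
#'   applications, default 50), Hebbian rates (`T_eps`, `T_g`, `T_rho`,
#'   `T_theta`, `k_eps`, `eta_g`, `normalize`), and anti-Hebbian settings
#'   (`anti_hebbian`, `target` — `"adaptive"` (default) balances each
#'   neuron's excitatory and inhibitory flux at their geometric mean,
#'   `"auto"` fixes a constant from the first window's mean excitatory
#'   flux, or a numeric constant; `mode` `"per_neuron"` or
#'   `"population"`).
#' @param store_phi Store the full flux trajectory (n x n x steps array);
#'   memory-heavy, intended for small diagnostic runs.
#' @return A `simulation_record`: trajectories `Q`, `V` (steps x n),
#'   per-neuron excitatory/inhibitory afferent flux sums `Se`, `Si`, the
#'   drive, gain snapshots `W_history` at every plasticity application,
#'   the per-application balance residuals, and the configuration echo.
#'   The first `burn_in` steps (max lag + kernel support) are flagged and
#'   excluded by downstream metrics.
#' @export
#' @examples
#' f <- build_field(list(n = 9, v = 1, seed = 1))
#' d <- white_noise_drive(9, 200, 0.2, seed = 2)
#' rec <- simulate_field(f, 200, drive = d)
#' range(rec$Q)
simulate_field <- function(field, steps, drive = NULL,
                           kernel = dendritic_kernel(2),
                           activation = activation_function(0, 1, 1),
                           plasticity = list(),
                           store_phi = FALSE) {
  stopifnot(inherits(field, "neural_field"), steps >= 0)
  pl <- merge_defaults(plasticity, default_plasticity())
  geo <- field$geometry
  n <- geo$n
  gains <- field$gains
  ecol <- geo$ei == "E"

  cfg_echo <- list(field = field$config, plasticity = pl, steps = steps,
                   kernel = list(tau = kernel$tau, support = kernel$support),
                   activation = unclass(activation))
  lag <- pmax(geo$delay, 1L)
  pad <- max(lag) + kernel$support

  rec <- structure(list(
    Q = matrix(numeric(0), 0, n), V = matrix(numeric(0), 0, n),
    Se = matrix(numeric(0), 0, n), Si = matrix(numeric(0), 0, n),
    drive = drive, geometry = geo, config = cfg_echo,
    burn_in = pad, W_history = list(list(step = 0L, W = gain_matrix(gains))),
    balance = data.frame(step = integer(), residual = numeric()),
    gains_init = gains, gains_final = gains,
    Phi = NULL, version = "cortigen-record-1"
  ), class = "simulation_record")
  if (steps == 0) return(rec)

  if (is.null(drive)) drive <- matrix(0, steps, n)
  if (nrow(drive) < steps || ncol(drive) != n)
    stop("invalid parameter: drive must be at least steps x n")

  kw <- kernel$weights
  sup <- kernel$support
  Qh <- matrix(0, pad + steps, n)
  Sh <- matrix(0, pad + steps, n)
  V <- matrix(0, steps, n)
  Se <- matrix(0, steps, n)
  Si <- matrix(0, steps, n)
  if (store_phi) Phi <- array(0, c(n, n, steps))

  W <- gain_matrix(gains)
  idx0 <- rep((seq_len(n) - 1L) * (pad + steps), each = n) + pad - lag
  cols <- rep(seq_len(n), each = n)
  ecols_mat <- matrix(ecol[cols], n, n)

  # plasticity window accumulators
  Cacc <- matrix(0, n, n); QDacc <- matrix(0, n, n); Qsum <- numeric(n)
  SEacc <- numeric(n); SIacc <- numeric(n); win <- 0L
  W_history <- rec$W_history
  balance <- list()
  target <- pl$target
  qmax <- activation$qmax

  for (t in seq_len(steps)) {
    r <- pad + t
    Qd <- matrix(Qh[idx0 + t], n, n)
    phi <- W * Qd
    phie <- phi; phie[!ecols_mat] <- 0
    se <- rowSums(phie)
    sall <- rowSums(phi)
    si <- sall - se
    s <- sall + drive[t, ]
    Sh[r, ] <- s
    Vt <- as.vector(kw %*% Sh[r - (0:sup), , drop = FALSE])
    Qt <- apply_activation(activation, Vt)
    if (any(!is.finite(Qt)))
      stop(sprintf("divergence error: non-finite state at step %d", t))
    Qh[r, ] <- Qt
    V[t, ] <- Vt
    Se[t, ] <- se
    Si[t, ] <- si
    if (store_phi) Phi[, , t] <- phi

    if (pl$enabled) {
      Cacc <- Cacc + Qt * Qd
      QDacc <- QDacc + Qd
      Qsum <- Qsum + Qt
      SEacc <- SEacc + se
      SIacc <- SIacc + si
      win <- win + 1L
      if (win == pl$period) {
        window <- list(coincidence = Cacc / win, pre_mean = QDacc / win,
                       post_mean = Qsum / win, steps = win, qmax = qmax)
        gains <- hebbian_update(gains, window, rates = pl)
        if (pl$anti_hebbian) {
          if (identical(target, "auto")) {
            target <- mean(SEacc / win)
            if (target <= 0) target <- 1
          }
          tgt <- if (identical(target, "adaptive"))
            balance_target(SEacc / win, SIacc / win)
          else target
          nb <- anti_hebbian_normalize(
            gains, list(sum_phi_e = SEacc / win, sum_phi_i = SIacc / win),
            target = tgt, ei = geo$ei,
            single_population = geo$single_population, mode = pl$mode)
          gains <- nb$gains
          balance[[length(balance) + 1L]] <-
            data.frame(step = t, residual = nb$residual)
        }
        W <- gain_matrix(gains)
        W_history[[length(W_history) + 1L]] <- list(step = t, W = W)
        Cacc[] <- 0; QDacc[] <- 0; Qsum[] <- 0
        SEacc[] <- 0; SIacc[] <- 0; win <- 0L
      }
    }
  }

  rec$Q <- Qh[pad + seq_len(steps), , drop = FALSE]
  rec$V <- V
  rec$Se <- Se
  rec$Si <- Si
  rec$drive <- drive
  rec$W_history <- W_history
  rec$balance <- if (length(balance)) do.call(rbind, balance)
                 else rec$balance
  rec$gains_final <- gains
  rec$config$plasticity$target <- target
  if (store_phi) rec$Phi <- Phi
  rec
}

default_plasticity <- function() {
  list(enabled = TRUE, period = 50L,
       T_eps = 10, T_g = 1000, T_rho = 10000, T_theta = 250,
       k_eps = 1, eta_g = 40, normalize = TRUE,
       anti_hebbian = TRUE, target = "adaptive", mode = "per_neuron")
}
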