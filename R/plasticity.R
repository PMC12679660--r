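#' Hebbian gain update on three timescales
#'
#' Applies one plasticity window to a `gain_state`.  The fast transient
#' efficacy `eps` relaxes (time constant `T_eps`) toward its baseline
#' scaled up by the window's pre/post pulse coincidence; the slow dynamic
#' gain `g` potentiates in proportion to `eps` times coincidence,
#' gated by a sliding (BCM-style) postsynaptic threshold, at rate set by
#' `T_g`; the structural gain `rho` is the slow exponential moving
#' average of `g` (time constant `T_rho`).  With `normalize = TRUE`,
#' competition bounds each postsynaptic row sum of `g` by its budget
#' (initial row sum times the configured headroom), by multiplicative
#' rescaling that preserves within-row ratios.
#'
#' The potentiation gate is `max(post_rate - theta, 0)` where the sliding
#' threshold `theta` tracks the square of the normalized postsynaptic
#' rate (time constant `T_theta`); with normalization off, `g` is
#' therefore non-decreasing under sustained positive coincident flux.
#'
#' @param gains A `gain_state`.
#' @param window A list with `coincidence` (n x n window mean of
#'   `Q_post(t) * Q_pre(t - lag)`), `pre_mean` (n x n window mean of the
#'   delayed presynaptic rate; optional, enables the covariance form of
#'   the coincidence drive), `post_mean` (length-n window mean
#'   postsynaptic rate), `steps` (window length, >= 1) and `qmax`.
#' @param rates A list of rate constants; see [simulate_field()]
#'   (`T_eps`, `T_g`, `T_rho`, `T_theta`, `k_eps`, `eta_g`, `normalize`).
#' @return The updated `gain_state` (carrying the updated sliding
#'   threshold in `$theta_bcm`).
#' @export
hebbian_update <- function(gains, window, rates = list()) {
  stopifnot(inherits(gains, "gain_state"))
  rates <- merge_defaults(rates, default_plasticity())
  L <- window$steps
  if (is.null(L) || L < 1) stop("invalid parameter: window length must be >= 1")
  qmax <- window$qmax %||% 1
  cn <- window$coincidence / qmax^2       # normalized coincidence in [0,1]
  post <- window$post_mean / qmax
  # Coincidence beyond chance: the pre/post covariance (coincidence
  # minus the product of window means) is the selective part of the
  # Hebbian drive; without pre_mean the raw coincidence is used.
  cv <- if (!is.null(window$pre_mean))
    pmax(cn - post * (window$pre_mean / qmax), 0)
  else cn
  # Heterosynaptic competition: only synapses whose coincidence exceeds
  # the neuron's average over its afferents potentiate, so the gain
  # pattern sharpens toward the most strongly co-active partners
  # instead of growing uniformly (gains are competitive on every
  # timescale).
  if (isTRUE(rates$normalize)) {
    naff <- rowSums(gains$mask)
    rowavg <- rowSums(cv * gains$mask) / pmax(naff, 1)
    cv <- pmax(cv - rowavg, 0)
  }

  a_eps <- 1 - exp(-L / rates$T_eps)
  a_g <- 1 - exp(-L / rates$T_g)
  a_rho <- 1 - exp(-L / rates$T_rho)
  a_th <- 1 - exp(-L / rates$T_theta)

  if (is.null(gains$theta_bcm)) gains$theta_bcm <- post^2
  gains$theta_bcm <- gains$theta_bcm + a_th * (post^2 - gains$theta_bcm)
  gate <- pmax(post - gains$theta_bcm, 0)

  gains$eps <- gains$eps +
    a_eps * (gains$eps0 * (1 + rates$k_eps * cn) * gains$mask - gains$eps)
  gains$g <- gains$g + rates$eta_g * a_g * (gains$eps * cv) * gate * gains$mask

  if (isTRUE(rates$normalize) && !is.null(gains$row_budget)) {
    rs <- rowSums(gains$g)
    over <- rs > gains$row_budget & rs > 0
    if (any(over))
      gains$g[over, ] <- gains$g[over, ] * (gains$row_budget[over] / rs[over])
  }

  # Structural consolidation: rho is the slow time average of g's
  # connection pattern, normalized to unit mean over existing synapses
  # (competition on the slowest timescale), so it consolidates relative
  # structure without rescaling the overall coupling.  Consolidation is
  # activity-dependent: a silent window leaves the structural gains
  # untouched.
  gm <- mean(gains$g[gains$mask])
  if (is.finite(gm) && gm > 0 && sum(cn) > 0)
    gains$rho <- gains$rho + a_rho * (gains$g / gm - gains$rho) * gains$mask
  gains
}

#' Anti-Hebbian excitatory/inhibitory normalization
#'
#' Homeostatic rescaling holding excitatory and inhibitory afferent flux
#' in balance: per postsynaptic neuron (or population-wide), the
#' excitatory gain block and the inhibitory gain block of `g` are each
#' multiplied by a scalar so that the window's summed excitatory flux and
#' the magnitude of the summed inhibitory flux both equal `target`.
#' Within-block gain ratios are unchanged to machine precision, so the
#' relative strengths of Hebbian influences are preserved.
#'
#' @param gains A `gain_state`.
#' @param window A list with `sum_phi_e` and `sum_phi_i`: per-neuron
#'   window means of total excitatory (positive) and inhibitory
#'   (negative) afferent flux.
#' @param target Desired flux magnitude (flux units, > 0); a scalar or a
#'   per-neuron vector.  Use [balance_target()] for the adaptive choice
#'   (geometric mean of the two blocks' window flux), which balances
#'   excitation against inhibition at the current activation level
#'   without rescaling the total coupling.
#' @param ei Per-neuron `"E"`/`"I"` labels (presynaptic types).
#' @param single_population Set when the field deliberately has one cell
#'   type; otherwise a field lacking either type raises an
#'   unbalanced-field error (balance is unachievable).
#' @param mode `"per_neuron"` (default) or `"population"`.
#' @return A list: `gains` (rescaled), `scale_e`, `scale_i`, and
#'   `residual` = max over neurons of `|sum_phi_e + sum_phi_i| / target`
#'   recomputed from the rescaled gains (zero up to rounding).  Neurons
#'   whose window flux in a block is exactly zero are left unscaled and
#'   excluded from the residual.
#' @export
anti_hebbian_normalize <- function(gains, window, target, ei,
                                   single_population = FALSE,
                                   mode = c("per_neuron", "population")) {
  stopifnot(inherits(gains, "gain_state"))
  mode <- match.arg(mode)
  if (any(!is.finite(target)) || any(target <= 0))
    stop("invalid parameter: target must be > 0")
  ecol <- ei == "E"
  if (!single_population && (!any(ecol) || all(ecol)))
    stop("unbalanced-field error: need both excitatory and inhibitory ",
         "neurons (or set single_population)")
  se <- window$sum_phi_e
  si <- window$sum_phi_i
  if (mode == "population") {
    se <- rep(mean(se), length(se))
    si <- rep(mean(si), length(si))
  }
  target <- rep_len(target, length(se))
  ok_e <- is.finite(se) & se > 0
  ok_i <- is.finite(si) & si < 0
  scale_e <- ifelse(ok_e, target / se, 1)
  scale_i <- ifelse(ok_i, target / abs(si), 1)
  gains$g[, ecol] <- gains$g[, ecol] * scale_e
  gains$g[, !ecol] <- gains$g[, !ecol] * scale_i
  ok <- ok_e & ok_i
  residual <- if (any(ok))
    max(abs(se[ok] * scale_e[ok] + si[ok] * scale_i[ok]) / target[ok])
  else NA_real_
  list(gains = gains, scale_e = scale_e, scale_i = scale_i,
       residual = residual, target = target)
}

#' Adaptive excitatory/inhibitory balance target
#'
#' The per-neuron geometric mean of the window's excitatory flux and
#' inhibitory flux magnitude.  Normalizing both blocks to this target
#' balances excitation against inhibition at the neuron's current
#' activation level while preserving the overall coupling magnitude, so
#' slow Hebbian growth — not the homeostatic constraint — sets the
#' field's maturation trajectory.
#'
#' @param sum_phi_e Per-neuron window mean excitatory flux (> 0).
#' @param sum_phi_i Per-neuron window mean inhibitory flux (< 0).
#' @param floor Minimum target (guards silent neurons), default 1e-12.
#' @return Per-neuron target vector.
#' @export
balance_target <- function(sum_phi_e, sum_phi_i, floor = 1e-12) {
  pmax(sqrt(pmax(sum_phi_e, 0) * pmax(-sum_phi_i, 0)), floor)
}
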