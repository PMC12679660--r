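#' Sigmoid pulse-generation function
#'
#' Builds the probabilistic threshold converting dendritic potential into
#' an action-potential pulse rate.  The logistic form is used: output is
#' bounded in `[0, qmax]`, equals `qmax/2` at the threshold midpoint
#' `theta`, and has derivative `slope` at the midpoint (so the linearized
#' small-signal model has tangent gain exactly `slope`).
#'
#' @param theta Threshold midpoint (potential units).
#' @param slope Derivative of the pulse rate at the midpoint
#'   (rate units per potential unit); must be positive.
#' @param qmax Maximum pulse rate; must be positive.
#' @return An object of class `activation_function`.
#' @export
#' @examples
#' act <- activation_function(theta = 0, slope = 1, qmax = 1)
#' apply_activation(act, 0)      # qmax/2
activation_function <- function(theta = 0, slope = 1, qmax = 1) {
  if (!is.finite(theta)) stop("invalid parameter: theta must be finite")
  if (!is.finite(slope) || slope <= 0) stop("invalid parameter: slope must be > 0")
  if (!is.finite(qmax) || qmax <= 0) stop("invalid parameter: qmax must be > 0")
  structure(list(theta = theta, slope = slope, qmax = qmax),
            class = "activation_function")
}

#' Evaluate an activation function
#'
#' @param act An `activation_function`.
#' @param v Numeric vector of dendritic potentials.
#' @return Pulse rates in `[0, qmax]`.
#' @export
apply_activation <- function(act, v) {
  stopifnot(inherits(act, "activation_function"))
  act$qmax / (1 + exp(-(4 * act$slope / act$qmax) * (v - act$theta)))
}

#' Dendritic integration kernel
#'
#' A single-exponential leaky-integrator kernel with time constant `tau`
#' (in time steps), truncated at `support` steps (default `5 * tau`) and
#' normalized to unit sum, so dendritic summation conserves mean flux.
#'
#' @param tau Dendritic time constant in time steps (> 0).
#' @param support Truncation length in steps (default `ceiling(5 * tau)`).
#' @return An object of class `dendritic_kernel` with a `weights` vector
#'   of length `support + 1`; `weights[k + 1]` multiplies flux from `k`
#'   steps in the past.
#' @export
#' @examples
#' k <- dendritic_kernel(tau = 2)
#' sum(k$weights)   # 1
dendritic_kernel <- function(tau = 2, support = NULL) {
  if (!is.finite(tau) || tau <= 0) stop("invalid parameter: tau must be > 0")
  support <- support %||% ceiling(5 * tau)
  support <- as.integer(support)
  if (support < 0) stop("invalid parameter: support must be >= 0")
  lam <- exp(-1 / tau)
  w <- lam^(0:support)
  w <- w / sum(w)
  structure(list(form = "exponential", tau = tau, support = support,
                 weights = w),
            class = "dendritic_kernel")
}
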