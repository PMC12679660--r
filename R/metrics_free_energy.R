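#' Mutual information of a Gaussian signal exchange
#'
#' The linear-approximation information shared by two signals with
#' correlation coefficient `r`: `-1/2 * log2(1 - r^2)` bits.  Symmetric
#' in the sign of `r` and monotone increasing in `|r|`.
#'
#' @param r Correlation coefficient(s).
#' @return Mutual information in bits; `+Inf` (with a warning) at
#'   `|r| = 1`.  `|r|` above 1 beyond numerical tolerance is an error.
#' @export
#' @examples
#' mutual_information(0.5)   # about 0.2075 bits
mutual_information <- function(r) {
  if (any(!is.finite(r))) stop("invalid-input error: r must be finite")
  if (any(abs(r) > 1 + 1e-9))
    stop("invalid-input error: |r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  if (any(abs(r) == 1))
    warning("|r| = 1: mutual information is infinite")
  -0.5 * log2(1 - r^2)
}

# cor(x(t), y(t - tau)) for tau = 0..K (normalized = TRUE), or the
# corresponding mean-product (covariance) values when normalized = FALSE.
# x, y must already be centered.
xcorr_lags <- function(x, y, K, sx, sy, normalized = TRUE) {
  L <- length(x)
  v <- vapply(0:K, function(tau) {
    sum(x[(1 + tau):L] * y[seq_len(L - tau)]) / (L - tau)
  }, numeric(1))
  if (normalized) v / (sx * sy) else v
}

#' Variational free energy of presynaptic flux
#'
#' Computes, over all connected cell pairs and lags `0..lag_range`, the
#' total flux autocorrelation `A`, the total cross-correlation `C`, the
#' variational free energy `F = A - C`, and the equilibrium residual:
#' the summed absolute difference between each pair's autocorrelation
#' total and cross-correlation total, which vanishes exactly when the
#' exchanged fluxes are identical (full synchrony).
#'
#' Correlation functions are computed on mean-subtracted (and, by
#' default, linearly detrended — slow gain growth otherwise masquerades
#' as correlation) flux.  With `normalized = TRUE` (default) the totals
#' are reported on the fractional scale: `A = 1` and
#' `C = C_raw / A_raw`, so `F = 1 - C_raw / A_raw` is the fraction of
#' the window's total flux autocorrelation not matched by
#' cross-correlation — flux-weighted (consolidated couplings dominate,
#' as their flux dominates the raw sums), invariant to overall gain
#' scale, and exactly 0 at full synchrony.  With `normalized = FALSE`
#' raw covariance sums are reported.
#'
#' @param record A `simulation_record`.  Flux series are taken from the
#'   stored `Phi` array when present, otherwise reconstructed from the
#'   pulse trajectory and gain snapshots.
#' @param lag_range Maximum lag in steps; default twice the maximum
#'   axonal delay.  Must be at least the maximum delay and smaller than
#'   the analysis window.
#' @param window Step range (default post-burn-in).
#' @param normalized Report on the fractional scale (default) or as raw
#'   covariance sums.
#' @param detrend Linearly detrend each flux series within the window
#'   (default TRUE).
#' @return An object of class `flux_statistics`: `A`, `C`, `F`,
#'   `eq8_residual`, `lag_range`, `n_pairs` (pairs with measurable
#'   flux), `sum_phi_e`, `sum_phi_i`.
#' @export
flux_free_energy <- function(record, lag_range = NULL, window = NULL,
                             normalized = TRUE, detrend = TRUE) {
  stopifnot(inherits(record, "simulation_record"))
  window <- window %||% post_burn_steps(record)
  maxd <- max(record$geometry$delay)
  lag_range <- lag_range %||% max(2L * maxd, 1L)
  if (lag_range < maxd)
    stop("invalid parameter: lag_range must cover the maximum axonal delay")
  if (lag_range >= length(window))
    stop("insufficient-data error: lag_range >= window length")

  mask <- record$gains_init$mask
  conn <- which(upper.tri(mask) & (mask | t(mask)), arr.ind = TRUE)
  A <- 0; C <- 0; resid <- 0; n_pairs <- 0L
  tt <- cbind(1, seq_along(window))
  for (e in seq_len(nrow(conn))) {
    i <- conn[e, 1]; j <- conn[e, 2]
    x <- pair_flux(record, i, j, window)
    y <- pair_flux(record, j, i, window)
    if (detrend) {
      x <- stats::residuals(stats::lm.fit(tt, x))
      y <- stats::residuals(stats::lm.fit(tt, y))
    } else {
      x <- x - mean(x)
      y <- y - mean(y)
    }
    sx <- sqrt(mean(x^2)); sy <- sqrt(mean(y^2))
    if (sx == 0 && sy == 0) next
    ax <- xcorr_lags(x, x, lag_range, sx, sx, FALSE)
    ay <- xcorr_lags(y, y, lag_range, sy, sy, FALSE)
    cxy <- xcorr_lags(x, y, lag_range, sx, sy, FALSE)
    cyx <- xcorr_lags(y, x, lag_range, sx, sy, FALSE)
    A <- A + sum(ax + ay)
    C <- C + sum(cxy + cyx)
    resid <- resid + sum(abs(ax + ay - cxy - cyx))
    n_pairs <- n_pairs + 1L
  }
  if (normalized) {
    if (A <= 0) stop("degenerate-variance error: no flux autocorrelation")
    C <- C / A
    resid <- resid / A
    A <- 1
  }
  structure(list(A = A, C = C, F = A - C, eq8_residual = resid,
                 lag_range = lag_range, n_pairs = n_pairs,
                 sum_phi_e = sum(record$Se[window, ]),
                 sum_phi_i = sum(record$Si[window, ]),
                 normalized = normalized),
            class = "flux_statistics")
}

pair_flux <- function(record, i, j, window) {
  if (!is.null(record$Phi)) record$Phi[i, j, window]
  else flux_series(record, i, j, window)
}

#' Windowed free-energy series of a record
#'
#' Splits the post-burn-in trajectory into `n_windows` equal windows and
#' evaluates [flux_free_energy()] in each; convenience input for
#' [free_energy_trajectory()].
#'
#' @inheritParams flux_free_energy
#' @param n_windows Number of windows (>= 3 for stability analysis).
#' @return A data frame with columns `window`, `F`, `A`, `C`,
#'   `eq8_residual`.
#' @export
windowed_free_energy <- function(record, n_windows = 8, lag_range = NULL,
                                 normalized = TRUE, detrend = TRUE) {
  idx <- post_burn_steps(record)
  cuts <- split(idx, cut(seq_along(idx), n_windows, labels = FALSE))
  rows <- lapply(seq_along(cuts), function(w) {
    fs <- flux_free_energy(record, lag_range, window = cuts[[w]],
                           normalized = normalized, detrend = detrend)
    data.frame(window = w, F = fs$F, A = fs$A, C = fs$C,
               eq8_residual = fs$eq8_residual)
  })
  do.call(rbind, rows)
}

#' Free-energy trajectory and fixed-point stability
#'
#' Finite-difference analysis of a windowed free-energy series: first
#' and second differences, and a stability classification.  The run is
#' classed `"unstable"` when the terminal free energy and its first
#' difference are both near zero (below `near_frac` of the initial free
#' energy) while the terminal second difference is positive — the
#' signature of approach to an unstable fixed point under residual
#' broken symmetry; otherwise `"stable"`.
#'
#' @param F_t Numeric vector of windowed free-energy values (>= 3).
#' @param near_frac Fraction of the initial `F` that counts as "near
#'   zero" (default 0.05).
#' @return An object of class `free_energy_trajectory`: `F_t`, `dF`,
#'   `d2F`, `stability_class`.
#' @export
#' @examples
#' free_energy_trajectory(c(4, 2, 1, 0.5))$stability_class
free_energy_trajectory <- function(F_t, near_frac = 0.05) {
  F_t <- as.numeric(F_t)
  if (length(F_t) < 3)
    stop("insufficient-windows error: need >= 3 windows")
  dF <- diff(F_t)
  d2F <- diff(F_t, differences = 2)
  near <- near_frac * abs(F_t[1])
  unstable <- abs(F_t[length(F_t)]) < near &&
    abs(dF[length(dF)]) < near &&
    d2F[length(d2F)] > 0
  structure(list(F_t = F_t, dF = dF, d2F = d2F,
                 stability_class = if (unstable) "unstable" else "stable",
                 near_frac = near_frac),
            class = "free_energy_trajectory")
}

#' Prediction-error residual between driven and baseline runs
#'
#' Operationalizes input neutralization: for two runs sharing geometry
#' and seed and differing only in drive (the baseline undriven), the
#' externally induced flux is the drive itself (`delta_plus`) and the
#' compensatory recurrent flux is the sign-reversed change in recurrent
#' afferent flux between the runs (`delta_minus`).  The per-step
#' residual `||delta_plus - delta_minus||` measures how completely the
#' network predicts and cancels its inputs.
#'
#' @param driven A `simulation_record` with external drive.
#' @param baseline The matched record with zero drive.
#' @return An object of class `prediction_error_report`: `delta_plus`,
#'   `delta_minus` (steps x n), `residual_norm` (per step), and its mean
#'   over post-burn-in steps.
#' @export
prediction_error_residual <- function(driven, baseline) {
  stopifnot(inherits(driven, "simulation_record"),
            inherits(baseline, "simulation_record"))
  if (driven$geometry$n != baseline$geometry$n ||
      !isTRUE(all.equal(driven$geometry$positions,
                        baseline$geometry$positions)) ||
      !identical(driven$geometry$delay, baseline$geometry$delay))
    stop("incompatible-records error: geometry differs between records")
  if (!is.null(baseline$drive) && any(baseline$drive != 0))
    stop("incompatible-records error: baseline record must be undriven")
  dp <- driven$drive %||% matrix(0, nrow(driven$Q), driven$geometry$n)
  dS <- (driven$Se + driven$Si) - (baseline$Se + baseline$Si)
  dm <- -dS
  rn <- sqrt(rowSums((dp - dm)^2))
  idx <- post_burn_steps(driven)
  structure(list(delta_plus = dp, delta_minus = dm, residual_norm = rn,
                 mean_residual = mean(rn[idx])),
            class = "prediction_error_report")
}

#' Channel capacity of a set of binary synaptic fluxes
#'
#' Shannon capacity `D = n * log2(1 + C/A)` bits for `n` binary-valued
#' flux channels with total cross-correlation `C` and total
#' autocorrelation `A` (`C/A` plays the role of a signal-to-noise
#' ratio); `D -> n` as `C -> A`.  Optionally splits the network into a
#' soft-wired component of `n_neo` fluxes and a hard-wired component of
#' `n_limb` fluxes and reports the distinguishable mirror-pair state
#' counts `2^(n/2)` and the number of soft-wired states available per
#' hard-wired state, `2^(n_neo - n_limb)`.
#'
#' @param n Number of flux channels (>= 1).
#' @param C Total cross-correlation (>= 0).
#' @param A Total autocorrelation (> 0).
#' @param n_neo,n_limb Optional component sizes with
#'   `n_neo + n_limb = n` and `n_neo > n_limb`.
#' @return An object of class `capacity_report`: `D` (bits),
#'   `states_mirror` (`2^(n/2)`, exact for exponents <= 62, otherwise
#'   `NA` with the log2 count in `log2_states_mirror`), and when the
#'   split is given, `states_per_limbic` with `log2_states_per_limbic`.
#' @export
#' @examples
#' channel_capacity(10, C = 1, A = 1)$D   # 10 bits
channel_capacity <- function(n, C, A, n_neo = NULL, n_limb = NULL) {
  if (n < 1) stop("invalid parameter: n must be >= 1")
  if (!is.finite(A) || A == 0) stop("undefined-ratio error: A must be nonzero")
  if (C < 0) stop("invalid parameter: C must be >= 0")
  D <- n * log2(1 + C / A)
  count_states <- function(expo) {
    if (expo <= 62) 2^expo else NA_real_
  }
  out <- list(n = n, C = C, A = A, D = D,
              states_mirror = count_states(n / 2),
              log2_states_mirror = n / 2)
  if (!is.null(n_neo) || !is.null(n_limb)) {
    if (is.null(n_neo) || is.null(n_limb) || n_neo + n_limb != n)
      stop("invalid parameter: n_neo + n_limb must equal n")
    if (n_neo <= n_limb)
      stop("invalid parameter: n_neo must exceed n_limb for state ratios")
    out$n_neo <- n_neo
    out$n_limb <- n_limb
    out$states_per_limbic <- count_states(n_neo - n_limb)
    out$log2_states_per_limbic <- n_neo - n_limb
  }
  structure(out, class = "capacity_report")
}

#' Channel capacity estimated from a simulation record
#'
#' Binarizes each connected pair's exchanged flux at its per-channel
#' median, accumulates the pairwise auto- and cross-correlation totals
#' over lags `0..lag_range`, and applies [channel_capacity()] with `n`
#' equal to the number of directed flux channels entering the sums.
#'
#' @inheritParams flux_free_energy
#' @return A `capacity_report`.
#' @export
capacity_from_record <- function(record, lag_range = NULL, window = NULL) {
  window <- window %||% post_burn_steps(record)
  maxd <- max(record$geometry$delay)
  lag_range <- lag_range %||% max(2L * maxd, 1L)
  mask <- record$gains_init$mask
  conn <- which(upper.tri(mask) & (mask | t(mask)), arr.ind = TRUE)
  A <- 0; C <- 0; nflux <- 0L
  for (e in seq_len(nrow(conn))) {
    i <- conn[e, 1]; j <- conn[e, 2]
    x <- pair_flux(record, i, j, window)
    y <- pair_flux(record, j, i, window)
    x <- as.numeric(x > stats::median(x))
    y <- as.numeric(y > stats::median(y))
    x <- x - mean(x); y <- y - mean(y)
    sx <- sqrt(mean(x^2)); sy <- sqrt(mean(y^2))
    if (sx == 0 || sy == 0) next
    A <- A + sum(xcorr_lags(x, x, lag_range, sx, sx, TRUE)) +
      sum(xcorr_lags(y, y, lag_range, sy, sy, TRUE))
    C <- C + sum(xcorr_lags(x, y, lag_range, sx, sy, TRUE)) +
      sum(xcorr_lags(y, x, lag_range, sx, sy, TRUE))
    nflux <- nflux + 2L
  }
  if (nflux == 0) stop("undefined-ratio error: no varying flux channels")
  channel_capacity(nflux, C = max(C, 0), A = A)
}
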