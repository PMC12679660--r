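#' @export
print.simulation_record <- function(x, ...) {
  cat("<simulation_record>", nrow(x$Q), "steps x", x$geometry$n,
      "neurons; burn-in", x$burn_in, "steps;",
      length(x$W_history) - 1L, "plasticity applications\n")
  invisible(x)
}

# Steps retained after burn-in.
post_burn_steps <- function(record) {
  b <- min(record$burn_in, nrow(record$Q))
  if (b == 0) seq_len(nrow(record$Q))
  else seq_len(nrow(record$Q))[-seq_len(b)]
}

# Effective connection weight matrix in force at step t (piecewise
# constant between plasticity applications).
weights_at <- function(record, t) {
  steps <- vapply(record$W_history, function(h) h$step, integer(1))
  record$W_history[[max(which(steps < t))]]$W
}

#' Reconstruct a pairwise presynaptic flux series
#'
#' Returns `phi_ij(t)` over a step range, rebuilt exactly from the stored
#' pulse-rate trajectory and the piecewise-constant gain snapshots:
#' `phi_ij(t) = W_ij(t) * Q_j(t - lag_ij)` with delayed samples before
#' the run taken as zero.
#'
#' @param record A `simulation_record`.
#' @param i Postsynaptic neuron index.
#' @param j Presynaptic neuron index.
#' @param window Integer step range (default: all post-burn-in steps).
#' @return Numeric vector of flux values.
#' @export
flux_series <- function(record, i, j, window = NULL) {
  window <- window %||% post_burn_steps(record)
  lag <- max(record$geometry$delay[i, j], 1L)
  tq <- window - lag
  qj <- ifelse(tq >= 1, record$Q[pmax(tq, 1L), j], 0)
  wsteps <- vapply(record$W_history, function(h) h$step, integer(1))
  wij <- vapply(record$W_history, function(h) h$W[i, j], numeric(1))
  idx <- findInterval(window - 1L, wsteps)
  wij[idx] * qj
}

#' Write a simulation record to disk
#'
#' Persists the record losslessly in a versioned native container (RDS).
#' Use [export_record_csv()] for a plain-text per-step summary.
#'
#' @param record A `simulation_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_record <- function(record, path) {
  stopifnot(inherits(record, "simulation_record"))
  saveRDS(record, path)
  invisible(path)
}

#' Read a simulation record from disk
#'
#' @param path File written by [save_record()].
#' @return The `simulation_record`.
#' @export
load_record <- function(path) {
  rec <- tryCatch(readRDS(path),
                  error = function(e) stop("corruption error: cannot read '",
                                           path, "': ", conditionMessage(e)))
  if (!inherits(rec, "simulation_record"))
    stop("format-version error: '", path, "' is not a simulation record")
  if (!identical(rec$version, "cortigen-record-1"))
    stop("format-version error: unsupported record version '",
         rec$version, "'")
  rec
}

#' Export per-step summaries of a record as CSV
#'
#' One row per post-burn-in step: mean/sd pulse rate, mean potential,
#' mean excitatory and inhibitory afferent flux, mean drive.
#'
#' @param record A `simulation_record`.
#' @param path Output CSV path.
#' @return The summary data frame, invisibly.
#' @export
export_record_csv <- function(record, path) {
  idx <- post_burn_steps(record)
  out <- data.frame(
    step = idx,
    mean_Q = rowMeans(record$Q[idx, , drop = FALSE]),
    sd_Q = apply(record$Q[idx, , drop = FALSE], 1, stats::sd),
    mean_V = rowMeans(record$V[idx, , drop = FALSE]),
    mean_phi_e = rowMeans(record$Se[idx, , drop = FALSE]),
    mean_phi_i = rowMeans(record$Si[idx, , drop = FALSE]),
    mean_drive = if (is.null(record$drive)) 0
                 else rowMeans(record$drive[idx, , drop = FALSE])
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
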