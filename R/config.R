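#' Default run configuration
#'
#' The complete configuration tree understood by the pipeline: field
#' geometry and gains, drive, kernel and activation, plasticity
#' schedule, morphogenesis and OP-map parameters, and the mandatory
#' seed.  [load_validate_config()] fills unspecified entries from these
#' defaults.
#'
#' @return A nested list.
#' @export
default_run_config <- function() {
  list(
    seed = NULL,                       # must be supplied explicitly
    steps = 2000L,
    field = default_field_config()[setdiff(names(default_field_config()),
                                           "seed")],
    drive = list(amplitude = 0.2),
    kernel = list(tau = 2),
    activation = list(theta = 0, slope = 1, qmax = 1),
    plasticity = default_plasticity(),
    morph = list(n_patch = 50L, n_local = 150L, axon_scale_patch = 6,
                 axon_scale_local = 1, w_synchrony = 1, w_wiring = 1,
                 max_iter = 2000L),
    opmap = list(k = 1, resolution = 0.05, n_maps = 1L),
    out_dir = ".",
    log_level = "info"
  )
}

#' Load and validate a JSON run configuration
#'
#' Parses a JSON configuration file, rejects unknown keys (strict mode)
#' with JSON-pointer paths, fills defaults, and applies range checks.
#' A seed is mandatory: no computation may be silently nondeterministic.
#'
#' @param path Path to a JSON file.
#' @param strict Reject unknown keys (default TRUE).
#' @return The validated configuration list, of class `run_config`.
#' @export
load_validate_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg, strict = strict)
}

#' Validate a configuration list
#'
#' @param cfg A configuration list (parsed JSON).
#' @param strict Reject unknown keys.
#' @return The merged, validated `run_config`.
#' @export
validate_config <- function(cfg, strict = TRUE) {
  defaults <- default_run_config()
  if (strict) check_unknown_keys(cfg, defaults, pointer = "")
  cfg <- restore_infinities(cfg)
  cfg <- merge_defaults(cfg, defaults)
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("config error at /seed: an explicit integer seed is required")
  checks <- list(
    list("/field/n", cfg$field$n >= 2, "n must be >= 2"),
    list("/field/v", is.finite(cfg$field$v) && cfg$field$v > 0,
         "conduction speed must be > 0"),
    list("/field/connection/density",
         cfg$field$connection$density > 0 && cfg$field$connection$density <= 1,
         "density must be in (0, 1]"),
    list("/drive/amplitude", cfg$drive$amplitude >= 0,
         "amplitude must be >= 0"),
    list("/kernel/tau", cfg$kernel$tau > 0, "tau must be > 0"),
    list("/activation/qmax", cfg$activation$qmax > 0, "qmax must be > 0"),
    list("/activation/slope", cfg$activation$slope > 0, "slope must be > 0"),
    list("/steps", cfg$steps >= 0, "steps must be >= 0"),
    list("/plasticity/period", cfg$plasticity$period >= 1,
         "period must be >= 1"),
    list("/morph/axon_scale_patch",
         cfg$morph$axon_scale_patch >= cfg$morph$axon_scale_local,
         "patch axon scale must be >= local axon scale"),
    list("/opmap/k", cfg$opmap$k > 0, "k must be > 0"),
    list("/opmap/resolution", cfg$opmap$resolution > 0,
         "resolution must be > 0")
  )
  for (ck in checks) {
    if (!isTRUE(ck[[2]]))
      stop("config error at ", ck[[1]], ": ", ck[[3]])
  }
  structure(cfg, class = c("run_config", "list"))
}

check_unknown_keys <- function(x, defaults, pointer) {
  if (!is.list(x) || is.null(names(x))) return(invisible())
  extra <- setdiff(names(x), c(names(defaults), "seed"))
  if (length(extra))
    stop("config error at ", pointer, "/", extra[1],
         ": unknown key (strict mode)")
  for (k in intersect(names(x), names(defaults))) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      check_unknown_keys(x[[k]], defaults[[k]], paste0(pointer, "/", k))
  }
  invisible()
}

# JSON has no infinities; they round-trip as strings.
restore_infinities <- function(x) {
  if (is.list(x)) return(lapply(x, restore_infinities))
  if (is.character(x) && length(x) == 1 && x %in% c("Inf", "-Inf"))
    return(as.numeric(x))
  x
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' Write a configuration in canonical JSON form
#'
#' Key order follows the default tree, so `dump_config(load_validate_config(p))`
#' is a canonical form: loading the dump reproduces the same
#' configuration exactly.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  cfg <- canonical_order(drop_nulls(cfg), default_run_config())
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

canonical_order <- function(x, defaults) {
  if (!is.list(x) || is.null(names(x))) return(x)
  keys <- c(intersect(names(defaults), names(x)),
            setdiff(names(x), names(defaults)))
  out <- x[keys]
  for (k in keys) {
    if (is.list(out[[k]]) && !is.null(names(defaults[[k]])))
      out[[k]] <- canonical_order(out[[k]], defaults[[k]])
  }
  out
}
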