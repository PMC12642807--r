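# Run configuration: YAML/JSON serialization with strict validation, so
# that no unvalidated number reaches the numeric core and every output
# can be regenerated from its config echo.

.sv_config_keys <- c("params", "init", "experiment", "solver", "sweep",
                     "seed", "outdir")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file. The only required section
#' is `params`, a flat mapping with exactly the [model_params()] field
#' names; it is validated on load (missing, unknown, or negative
#' entries are rejected with the offending field named). Optional
#' sections: `init` (biomass 4-vector), `experiment` (fields
#' `compartments`, `propagule`), `solver` (fields `horizon`, `n_out`,
#' `max_time`), `sweep` (fields `edge`, `alpha_range`, `beta_range`,
#' `grid`), `seed`, `outdir`. Unknown top-level keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `sv_config` with a validated `params`
#'   element of class `sv_params`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_config(raw)
}

#' @rdname load_config
#' @param x a raw configuration list.
#' @export
as_config <- function(x) {
  if (!is.list(x)) stop("configuration must be a mapping", call. = FALSE)
  unknown <- setdiff(names(x), .sv_config_keys)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(x$params))
    stop("configuration must contain a 'params' mapping", call. = FALSE)
  pl <- as.list(x$params)
  miss <- setdiff(.sv_param_names, names(pl))
  if (length(miss) > 0L)
    stop("missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  params <- do.call(model_params, pl)
  cfg <- x
  cfg$params <- params
  if (!is.null(cfg$init)) cfg$init <- check_state(unlist(cfg$init))
  if (!is.null(cfg$seed)) {
    s <- cfg$seed
    if (!is.numeric(s) || length(s) != 1L || s != round(s))
      stop("'seed' must be a single integer", call. = FALSE)
    cfg$seed <- as.integer(s)
  }
  structure(cfg, class = "sv_config")
}

#' Write a configuration (or parameter set) to file
#'
#' Round-trips losslessly through [load_config()]: numbers are written
#' at full precision.
#'
#' @param config an `sv_config`, or an [model_params()] object (wrapped
#'   as a params-only configuration).
#' @param path output path ending in `.yaml`, `.yml`, or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "sv_params")) config <- list(params = config)
  out <- unclass(config)
  out$params <- as.list(unclass(out$params))
  if (!is.null(out$init)) out$init <- as.list(out$init)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 17L)
  }
  invisible(path)
}
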