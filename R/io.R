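# JSON run-configuration and policy-container serialization.
#
# Policies are stored as a versioned JSON container (datasets: times, grid,
# V, A, gap; the fully-resolved config embedded alongside a checksum). JSON
# keeps the container plain-text and dependency-light; numbers are written
# at full precision.

run_config_keys <- c("regime", "cost_regime", "n_options", "c", "rho", "t_w",
                     "gamma", "dt", "horizon", "grid_lo", "grid_hi",
                     "grid_n", "utility", "belief", "utility_mode",
                     "sim_dt", "n", "seed")
utility_keys <- c("family", "m", "s")
belief_keys <- c("prior_mean", "prior_var", "obs_var")

utility_from_list <- function(u) {
  bad <- setdiff(names(u), utility_keys)
  if (length(bad) > 0L)
    stop("unknown utility keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(u$family)) stop("utility needs a 'family'", call. = FALSE)
  switch(u$family,
    linear = utility_linear(),
    logistic = utility_logistic(m = u$m, s = u$s),
    stop("unknown utility family: ", u$family, call. = FALSE))
}

utility_to_list <- function(u) {
  switch(u$family,
    linear = list(family = "linear"),
    logistic = list(family = "logistic", m = u$m, s = u$s),
    stop("utility family '", u$family, "' cannot be serialized",
         call. = FALSE))
}

config_from_list <- function(lst) {
  bad <- setdiff(names(lst), run_config_keys)
  if (length(bad) > 0L)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  regime <- lst$cost_regime %||% lst$regime %||% "linear"
  utility <- if (is.null(lst$utility)) utility_linear()
             else utility_from_list(lst$utility)
  belief <- lst$belief %||% list()
  bad <- setdiff(names(belief), belief_keys)
  if (length(bad) > 0L)
    stop("unknown belief keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg_args <- list(
    n_options = lst$n_options %||% 3L,
    cost_regime = regime,
    dt = lst$dt %||% 0.05,
    horizon = lst$horizon %||% 3,
    grid_lo = lst$grid_lo %||% -5,
    grid_hi = lst$grid_hi %||% 5,
    grid_n = lst$grid_n %||% 41L,
    utility = utility,
    prior_mean = belief$prior_mean %||% 1.5,
    prior_var = belief$prior_var %||% 5,
    obs_var = belief$obs_var %||% 2,
    utility_mode = lst$utility_mode %||% "point")
  if (regime == "geometric") {
    cfg_args$gamma <- lst$gamma
  } else {
    cfg_args$c <- lst$c %||% 0
    cfg_args$rho <- lst$rho
    cfg_args$t_w <- lst$t_w %||% 1
  }
  cfg <- do.call(bellman_config, cfg_args)
  structure(list(config = cfg,
                 sim_dt = lst$sim_dt %||% 5e-3,
                 n = lst$n %||% 10000L,
                 seed = lst$seed),
            class = "run_config")
}

config_to_list <- function(rc) {
  cfg <- if (inherits(rc, "run_config")) rc$config else rc
  out <- list(
    cost_regime = cfg$cost_regime,
    n_options = cfg$n_options,
    dt = cfg$dt, horizon = cfg$horizon,
    grid_lo = cfg$grid_lo, grid_hi = cfg$grid_hi, grid_n = cfg$grid_n,
    utility = utility_to_list(cfg$utility),
    belief = list(prior_mean = cfg$prior_mean, prior_var = cfg$prior_var,
                  obs_var = cfg$obs_var),
    utility_mode = cfg$utility_mode)
  if (cfg$cost_regime == "geometric") {
    out$gamma <- cfg$gamma
  } else {
    out$c <- cfg$c
    out$t_w <- cfg$t_w
    if (!is.null(cfg$rho)) out$rho <- cfg$rho
  }
  if (inherits(rc, "run_config")) {
    out$sim_dt <- rc$sim_dt
    out$n <- rc$n
    if (!is.null(rc$seed)) out$seed <- rc$seed
  }
  out
}

#' Load and validate a run configuration
#'
#' Reads a JSON run configuration, fills the documented defaults (prior
#' N(1.5, 5), observation noise variance 2, 41-point grid on [-5, 5],
#' dt = 0.05, horizon 3, sim_dt = 5e-3), and rejects unknown keys. See
#' [bellman_config()] for the schema of the dynamic-programming fields;
#' additionally `sim_dt`, `n` and `seed` configure simulation runs.
#'
#' @param path Path to a JSON file.
#' @return An object of class `run_config`: list with the validated
#'   `config` ([bellman_config()]), `sim_dt`, `n` and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  config_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Save a resolved run configuration
#'
#' Writes the fully-resolved configuration (all defaults filled) as JSON, so
#' every run is reproducible from the saved file and a seed alone.
#'
#' @param rc A `run_config` or [bellman_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(rc, path) {
  jsonlite::write_json(config_to_list(rc), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Stable content checksum for the embedded config (no external digest
# dependency): polynomial hash of the canonical JSON text.
config_checksum <- function(lst) {
  txt <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (v in utf8ToInt(as.character(txt))) h <- (h * 31 + v) %% 2147483647
  h
}

policy_schema <- "valuedp-policy"
policy_schema_version <- 1L

#' Save / load a solved policy
#'
#' Serializes a `policy_grid` to a versioned JSON container holding the time
#' slices, value function, action labels, stop-continue gaps, grid and the
#' fully-resolved configuration (with checksum). The round trip is lossless
#' up to double-precision text formatting.
#'
#' @param p A `policy_grid` from [solve_policy()].
#' @param path File path of the container.
#' @return `save_policy` returns `path` invisibly; `load_policy` returns the
#'   `policy_grid`.
#' @export
save_policy <- function(p, path) {
  stopifnot(inherits(p, "policy_grid"))
  cfg_list <- config_to_list(p$config)
  obj <- list(
    schema = policy_schema,
    schema_version = policy_schema_version,
    config = cfg_list,
    config_checksum = config_checksum(cfg_list),
    times = p$times,
    grid = p$grid,
    dims = dim(p$V[[1L]]),
    V = lapply(p$V, as.vector),
    A = lapply(p$A, as.vector),
    gap = lapply(p$gap, as.vector))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  if (!file.exists(path)) stop("policy file not found: ", path,
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, policy_schema))
    stop("not a valuedp policy container: ", path, call. = FALSE)
  if (!identical(as.integer(obj$schema_version), policy_schema_version))
    stop(sprintf("policy container schema version %s is not supported",
                 obj$schema_version), call. = FALSE)
  for (ds in c("config", "times", "grid", "dims", "V", "A", "gap"))
    if (is.null(obj[[ds]]))
      stop("policy container is missing dataset '", ds, "'", call. = FALSE)
  stored_sum <- obj$config_checksum
  if (!is.null(stored_sum) &&
      !identical(config_checksum(obj$config), as.numeric(stored_sum)))
    stop("embedded config checksum mismatch", call. = FALSE)
  rc <- config_from_list(obj$config)
  dims <- as.integer(obj$dims)
  to_arrays <- function(x, mode) lapply(x, function(v)
    array(as.vector(v, mode = mode), dims))
  # read_json simplifies lists of equal-length vectors to a matrix
  as_list <- function(x) if (is.matrix(x)) asplit(x, 1L) else x
  structure(list(times = as.numeric(obj$times),
                 V = to_arrays(as_list(obj$V), "double"),
                 A = to_arrays(as_list(obj$A), "integer"),
                 gap = to_arrays(as_list(obj$gap), "double"),
                 grid = as.numeric(obj$grid),
                 config = rc$config),
            class = "policy_grid")
}

#' Write a boundary slice as CSV
#'
#' @param slice A [project_boundary_slice()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(slice, path) {
  stopifnot(inherits(slice, "boundary_slice"))
  utils::write.csv(as.data.frame(slice), path, row.names = FALSE)
  invisible(path)
}
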