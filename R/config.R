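#' Pipeline run configuration
#'
#' A run configuration bundles everything a full pipeline run needs: the
#' model parameters, solver settings, scenario selection, observable
#' conversion settings, synthetic-cohort settings and the sensitivity
#' block, plus one master seed from which every stochastic stage derives
#' its own sub-seed deterministically. `default_config()` reproduces the
#' published calibration; configurations round-trip through YAML
#' (`load -> dump -> load` gives an equal configuration).
#'
#' @return `default_config()` returns a named list with components
#'   `params`, `solver` (`horizon`, and optionally `hstep`; omitted means
#'   the stable step is chosen automatically), `scenario` (`"all"` or one
#'   arm), `injection_day`, `observables` (`cell_diameter`, `packing`),
#'   `synthetic` (`n_mice`, `days`, `noise_sigma`, `mouse_cv`),
#'   `sensitivity` (`n`, `span`, `dose_lower`, `dose_upper`, `alpha`,
#'   `output_every_dt`, `use_fit_ranges`) and `seed`.
#' @export
default_config <- function() {
  list(
    params = unclass(model_params())[param_field_names()],
    solver = list(horizon = 100),
    scenario = "all",
    injection_day = 3,
    observables = list(cell_diameter = 0.02, packing = 1),
    synthetic = list(n_mice = 5, days = seq(6, 30, by = 3),
                     noise_sigma = 0.05, mouse_cv = 0.05),
    sensitivity = list(n = 1000, span = 0.5, dose_lower = 0.25,
                       dose_upper = 2, alpha = 0.01, output_every_dt = 3,
                       use_fit_ranges = TRUE),
    seed = 1
  )
}

config_schema <- function() {
  list(
    params = param_field_names(),
    solver = c("hstep", "horizon"),
    scenario = NULL,
    injection_day = NULL,
    observables = c("cell_diameter", "packing"),
    synthetic = c("n_mice", "days", "noise_sigma", "mouse_cv"),
    sensitivity = c("n", "span", "dose_lower", "dose_upper", "alpha",
                    "output_every_dt", "use_fit_ranges"),
    seed = NULL
  )
}

#' Validate a run configuration
#'
#' Fills unspecified keys with their defaults, then checks that no unknown
#' keys remain (a schema error lists every offending key), that the
#' parameter block passes [validate_params()], and that the scenario label
#' is valid.
#'
#' @param config A configuration list (see [default_config()]).
#' @return The completed configuration, invisibly usable downstream.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  schema <- config_schema()
  bad <- setdiff(names(config), names(schema))
  for (key in intersect(names(config), names(schema))) {
    allowed <- schema[[key]]
    if (!is.null(allowed) && is.list(config[[key]])) {
      extra <- setdiff(names(config[[key]]), allowed)
      bad <- c(bad, if (length(extra) > 0) paste0(key, "$", extra))
    }
  }
  if (length(bad) > 0) {
    stop("schema error: unknown configuration key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- utils::modifyList(default_config(), config)
  do.call(model_params, full$params) # validates the parameter block
  if (!full$scenario %in% c("all", scenario_names())) {
    stop("schema error: scenario must be 'all' or one of: ",
         paste(scenario_names(), collapse = ", "), call. = FALSE)
  }
  if (!is.null(full$solver$hstep) && full$solver$hstep <= 0) {
    stop("schema error: solver hstep must be positive (or omitted for auto)",
         call. = FALSE)
  }
  if (full$solver$horizon <= 0) {
    stop("schema error: solver horizon must be positive", call. = FALSE)
  }
  full
}

#' Read and write run configurations as YAML
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_run_config()` returns the validated configuration;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- rapply(yaml::read_yaml(path), how = "replace", f = function(x) {
    if (is.integer(x)) as.numeric(x) else x
  })
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  out <- rapply(config, how = "replace", f = function(x) {
    if (is.numeric(x) && !is.integer(x)) yaml_number(x) else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

# Deterministic sub-seed derivation: every stochastic stage gets its own
# stream from the single master seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647)
}
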