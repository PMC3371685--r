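#' Model parameters for the melanoma--immune competition model
#'
#' Constructs the full parameter set of the two-compartment delay
#' differential equation model. Defaults are the published calibration for
#' the B16-OVA melanoma / OT1 CTL / anti-CD137 antibody system. All rates
#' are expressed per time step \eqn{\Delta t} (one step = `dt_hours` hours,
#' 8 by default), so a rate of 0.1 means 10% per 8 hours.
#'
#' @param alpha1 Gompertz growth rate of melanoma cells, per \eqn{\Delta t}.
#' @param alpha2 Gompertz shrink rate, per \eqn{\Delta t}. The tumour
#'   plateau (carrying level) is `exp(alpha1/alpha2)` cells.
#' @param alpha3 Maximum killing rate of melanoma cells by skin-resident
#'   activated CTLs, per cell per \eqn{\Delta t}.
#' @param alpha4 Antigen release rate per killed melanoma cell.
#' @param alpha5 Antigen natural degradation rate, per \eqn{\Delta t}.
#' @param alpha6 Switch rate from naive to activated CTLs per antigen,
#'   per \eqn{\Delta t}.
#' @param alpha7 Maximum duplication rate of skin-resident activated CTLs,
#'   per \eqn{\Delta t}.
#' @param alpha8 Natural death rate of activated CTLs (both compartments),
#'   per \eqn{\Delta t}.
#' @param alpha9 Antibody consumption rate per activated CTL in the skin,
#'   per \eqn{\Delta t}.
#' @param alpha10 Antibody natural degradation rate (both compartments),
#'   per \eqn{\Delta t}.
#' @param alpha11 Migration rate from the injection-point compartment to
#'   the skin compartment, per \eqn{\Delta t}.
#' @param h Repopulation rate of naive CTLs by the thymus, per
#'   \eqn{\Delta t}.
#' @param k1 Half-saturation antibody count of the Holling type II
#'   CTL-duplication response.
#' @param k2,k3 Minimum- and maximum-killing antibody thresholds of the
#'   antibody-modulated killing factor; `k2 < k3` is required (killing in
#'   the absence of antibodies is reduced by the factor `k2/k3`).
#' @param M Number of antigen-specific naive CTLs under safe conditions.
#' @param C0 Initial number of injected melanoma cells.
#' @param p Number of activated OT1 CTLs injected per treatment bolus.
#' @param q Number of anti-CD137 antibodies injected per treatment bolus.
#' @param tau Migration delay between compartments, in \eqn{\Delta t}
#'   units (1 unit = `dt_hours` hours).
#' @param dt_hours Physical duration of one \eqn{\Delta t} unit, in hours.
#'
#' @return An object of class `melimm_params`: a named list of the 21
#'   parameters above.
#' @seealso [read_params()], [write_params()], [melanoma_rhs()],
#'   [integrate_model()]
#' @examples
#' params <- model_params()
#' params$alpha1
#' # carrying level of the Gompertz law, in cells:
#' exp(params$alpha1 / params$alpha2)
#' @export
model_params <- function(alpha1 = 0.2165,
                         alpha2 = 0.01269,
                         alpha3 = 0.00000033,
                         alpha4 = 0.21,
                         alpha5 = log(2) / 9,
                         alpha6 = 0.1,
                         alpha7 = 0.095,
                         alpha8 = log(2) / 15,
                         alpha9 = 0.000001,
                         alpha10 = log(2) / 21,
                         alpha11 = 0.009,
                         h = 0.01,
                         k1 = 10,
                         k2 = 1,
                         k3 = 50,
                         M = 196000,
                         C0 = 180000,
                         p = 760000,
                         q = 1000000,
                         tau = 1,
                         dt_hours = 8) {
  params <- list(
    alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, alpha4 = alpha4,
    alpha5 = alpha5, alpha6 = alpha6, alpha7 = alpha7, alpha8 = alpha8,
    alpha9 = alpha9, alpha10 = alpha10, alpha11 = alpha11,
    h = h, k1 = k1, k2 = k2, k3 = k3,
    M = M, C0 = C0, p = p, q = q, tau = tau, dt_hours = dt_hours
  )
  class(params) <- "melimm_params"
  validate_params(params)
  params
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model parameters: every rate,
#' count and threshold must be non-negative and finite, the killing
#' thresholds must satisfy `k2 < k3`, the shrink rate `alpha2` must be
#' strictly positive (the Gompertz plateau is otherwise undefined), and the
#' delay `tau` must be non-negative.
#'
#' @param params A `melimm_params` object or a named list with the same
#'   fields.
#' @return `params`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(params) {
  fields <- param_field_names()
  missing <- setdiff(fields, names(params))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(params[fields])
  if (!all(is.finite(vals))) {
    stop("all parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- fields[vals < 0]
    stop("negative parameter value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (params$alpha2 <= 0) {
    stop("alpha2 must be strictly positive", call. = FALSE)
  }
  if (params$k2 >= params$k3) {
    stop("invalid thresholds: k2 must be strictly less than k3 (k2 << k3)",
         call. = FALSE)
  }
  if (params$dt_hours <= 0) {
    stop("dt_hours must be strictly positive", call. = FALSE)
  }
  invisible(params)
}

param_field_names <- function() {
  c(paste0("alpha", 1:11), "h", "k1", "k2", "k3",
    "M", "C0", "p", "q", "tau", "dt_hours")
}

#' @export
print.melimm_params <- function(x, ...) {
  cat("<melimm_params> melanoma-immune DDE model parameters\n")
  cat(sprintf("  time unit: 1 dt = %g h; delay tau = %g dt\n",
              x$dt_hours, x$tau))
  cat(sprintf("  Gompertz: alpha1 = %g, alpha2 = %g (plateau %.4g cells)\n",
              x$alpha1, x$alpha2, exp(x$alpha1 / x$alpha2)))
  cat(sprintf("  doses: p = %g CTLs, q = %g antibodies; C0 = %g, M = %g\n",
              x$p, x$q, x$C0, x$M))
  other <- setdiff(param_field_names(),
                   c("alpha1", "alpha2", "p", "q", "C0", "M",
                     "tau", "dt_hours"))
  cat("  rates/thresholds:",
      paste(sprintf("%s=%g", other, unlist(x[other])), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read and write model parameters as YAML
#'
#' A parameter set serializes to a flat key--value YAML file. The packaged
#' default file (`system.file("extdata", "table2-params.yaml", package =
#' "melimm")`) reproduces the published calibration exactly; numbers are
#' written with 17 significant digits so the round trip is bit-exact.
#'
#' @param path File path of the YAML file.
#' @param params A `melimm_params` object.
#' @return `read_params()` returns a `melimm_params` object;
#'   `write_params()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_params(model_params(), path)
#' identical(read_params(path), model_params())
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), param_field_names())
  if (length(extra) > 0) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(model_params, lapply(raw, as.numeric))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  flat <- lapply(unclass(params)[param_field_names()], yaml_number)
  yaml::write_yaml(flat, path)
  invisible(path)
}

# Emit a double as a 17-significant-digit plain YAML scalar, so reading the
# file back reproduces the binary value exactly (the yaml emitter itself
# caps at 16 digits).
yaml_number <- function(x) {
  if (length(x) == 1) {
    structure(sprintf("%.17g", x), class = "verbatim")
  } else {
    lapply(x, yaml_number)
  }
}

#' Time unit conversions
#'
#' The model is integrated in \eqn{\Delta t} units (8-hour steps by
#' default); reporting is in days. These helpers convert between the two.
#'
#' @param t_dt Time in \eqn{\Delta t} units.
#' @param days Time in days.
#' @param dt_hours Hours per \eqn{\Delta t} unit.
#' @return A numeric vector of converted times.
#' @examples
#' dt_to_days(100) # the default 100-step horizon in days
#' days_to_dt(3)   # the day-3 injection time in dt units
#' @export
dt_to_days <- function(t_dt, dt_hours = 8) t_dt * dt_hours / 24

#' @rdname dt_to_days
#' @export
days_to_dt <- function(days, dt_hours = 8) days * 24 / dt_hours
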