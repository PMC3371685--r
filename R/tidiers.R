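#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gompertz fit
#'
#' @param x A `gompertz_fit` object.
#' @param ... Unused.
#' @return One row per fitted term (`alpha1`, `alpha2`, and `lnC0` when the
#'   initial burden was estimated) with `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.gompertz_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.gompertz_fit
#' @return `glance()` returns a one-row tibble with the fit-level summary:
#'   residual `sigma` on the log scale, `nobs`, the implied plateau in
#'   cells, and the `wide_ci` identifiability flag.
#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble::tibble(
    alpha1 = x$alpha1_hat,
    alpha2 = x$alpha2_hat,
    C0 = x$C0,
    plateau_cells = exp(x$alpha1_hat / x$alpha2_hat),
    sigma = x$sigma,
    nobs = x$nobs,
    df.residual = x$nobs - nrow(x$coefficients),
    wide_ci = x$wide_ci
  )
}

#' Tidy a PRCC timecourse
#'
#' @param x A `prcc_timecourse` object.
#' @param ... Unused.
#' @return `tidy()` returns the long table (time, parameter, prcc,
#'   p_value, significant) as a plain tibble; `glance()` a one-row summary
#'   of the run.
#' @export
tidy.prcc_timecourse <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.prcc_timecourse
#' @export
glance.prcc_timecourse <- function(x, ...) {
  tibble::tibble(
    scenario = attr(x, "scenario"),
    output = attr(x, "output"),
    n_samples = attr(x, "n_samples"),
    n_failed = attr(x, "n_failed"),
    n_parameters = length(unique(x$parameter)),
    n_times = length(unique(x$time_dt)),
    alpha = attr(x, "alpha"),
    seed = attr(x, "seed") %||% NA_integer_
  )
}
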