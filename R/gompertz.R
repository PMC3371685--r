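#' Closed-form Gompertz growth curve
#'
#' Exact solution of the scalar growth law
#' `dC/dt = (alpha1 - alpha2 * log(C)) * C`:
#' `C(t) = exp(log(K) - (log(K) - log(C0)) * exp(-alpha2 * t))` with
#' carrying level `K = exp(alpha1 / alpha2)`. This is the untreated-tumour
#' oracle: with an empty schedule the full DDE system reduces to this
#' single equation.
#'
#' @param t Time(s) in \eqn{\Delta t} units, non-negative.
#' @param C0 Initial cell count, at least 1.
#' @param alpha1 Gompertz growth rate, per \eqn{\Delta t}.
#' @param alpha2 Gompertz shrink rate, per \eqn{\Delta t}, strictly
#'   positive.
#' @return Cell count(s) at `t`.
#' @examples
#' p <- model_params()
#' gompertz_closed_form(0, p$C0, p$alpha1, p$alpha2)    # = C0
#' gompertz_closed_form(1e6, p$C0, p$alpha1, p$alpha2)  # ~ the plateau
#' @export
gompertz_closed_form <- function(t, C0, alpha1, alpha2) {
  if (!is.numeric(C0) || length(C0) != 1 || C0 < 1) {
    stop("C0 must be a single count >= 1", call. = FALSE)
  }
  if (alpha2 <= 0) stop("alpha2 must be strictly positive", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  lnK <- alpha1 / alpha2
  exp(lnK - (lnK - log(C0)) * exp(-alpha2 * t))
}

#' Fit Gompertz growth parameters to count measurements
#'
#' Estimates `(alpha1, alpha2)` (and, unless supplied, the initial burden
#' `C0`) by nonlinear least squares of the closed-form Gompertz curve
#' against log-counts. Fitting on the log scale treats measurement error as
#' multiplicative, which is the natural model for counts derived from
#' measured areas. Confidence ranges are normal-approximation intervals
#' from the least-squares covariance; they are the ranges later used to
#' sample `alpha1` and `alpha2` in the sensitivity analysis.
#'
#' Starting values are deterministic: `alpha2` from the slope of the log of
#' successive log-count increments (the increments of `log C` decay like
#' `exp(-alpha2 t)`), `alpha1 = alpha2 * log(max(count))`, and `C0`
#' back-extrapolated from the earliest observation.
#'
#' @param data A data frame of measurements.
#' @param time,count Names of the time (in \eqn{\Delta t} units) and count
#'   columns in `data`.
#' @param C0 Known initial cell count; if `NULL` (default) it is estimated
#'   as a third parameter.
#' @param level Confidence level for the parameter ranges (default 0.95).
#' @return A `gompertz_fit` object; see [tidy.gompertz_fit()] and
#'   [glance.gompertz_fit()] for tidy summaries. The element `wide_ci` is
#'   `TRUE` when the covariance was singular (unidentifiable fit, e.g. all
#'   observations at the plateau) and the ranges are unbounded.
#' @examples
#' p <- model_params()
#' times <- seq(10, 100, by = 10)
#' df <- data.frame(time_dt = times,
#'                  cells = gompertz_closed_form(times, p$C0, p$alpha1, p$alpha2))
#' fit <- fit_gompertz(df)
#' tidy(fit)
#' @export
fit_gompertz <- function(data, time = "time_dt", count = "cells",
                         C0 = NULL, level = 0.95) {
  if (!is.data.frame(data)) stop("data must be a data frame", call. = FALSE)
  if (!all(c(time, count) %in% names(data))) {
    stop(sprintf("data needs columns '%s' and '%s'", time, count),
         call. = FALSE)
  }
  t <- as.numeric(data[[time]])
  cts <- as.numeric(data[[count]])
  keep <- is.finite(t) & is.finite(cts)
  t <- t[keep]; cts <- cts[keep]
  if (any(cts < 1)) {
    stop("counts must be >= 1 (log-scale fit)", call. = FALSE)
  }
  if (length(unique(t)) < 3) {
    stop("insufficient data: need measurements at >= 3 distinct times",
         call. = FALSE)
  }
  logc <- log(cts)
  start <- gompertz_start(t, logc)
  df <- data.frame(t = t, logc = logc)

  estimate_c0 <- is.null(C0)
  fit <- tryCatch({
    if (estimate_c0) {
      minpack.lm::nlsLM(
        logc ~ a1 / a2 - (a1 / a2 - lc0) * exp(-a2 * t),
        data = df,
        start = list(a1 = start$alpha1, a2 = start$alpha2, lc0 = start$lnC0),
        lower = c(a1 = 1e-8, a2 = 1e-8, lc0 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      )
    } else {
      lc0 <- log(C0)
      minpack.lm::nlsLM(
        logc ~ a1 / a2 - (a1 / a2 - lc0) * exp(-a2 * t),
        data = df,
        start = list(a1 = start$alpha1, a2 = start$alpha2),
        lower = c(a1 = 1e-8, a2 = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      )
    }
  }, error = function(e) {
    stop("fit-failure: nonlinear least squares did not converge (",
         conditionMessage(e), ")", call. = FALSE)
  })

  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc) || any(!is.finite(diag(vc)))) {
    rep(Inf, length(est))
  } else {
    sqrt(pmax(diag(vc), 0))
  }
  wide_ci <- any(!is.finite(se)) || any(se > 10 * pmax(abs(est), 1e-12))
  z <- stats::qnorm(1 - (1 - level) / 2)
  terms <- c("alpha1", "alpha2", if (estimate_c0) "lnC0")
  coefs <- tibble::tibble(
    term = terms,
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  res <- stats::resid(fit)
  structure(list(
    coefficients = coefs,
    alpha1_hat = unname(est[["a1"]]),
    alpha2_hat = unname(est[["a2"]]),
    C0 = if (estimate_c0) exp(unname(est[["lc0"]])) else C0,
    C0_estimated = estimate_c0,
    level = level,
    sigma = sqrt(sum(res^2) / max(1, length(res) - length(est))),
    residuals = res,
    nobs = length(t),
    data = tibble::tibble(time_dt = t, cells = cts),
    wide_ci = wide_ci,
    fit = fit
  ), class = "gompertz_fit")
}

# Deterministic starting values for the log-scale Gompertz fit.
gompertz_start <- function(t, logc) {
  o <- order(t)
  t <- t[o]; logc <- logc[o]
  dl <- diff(logc) / diff(t)
  mid <- (t[-1] + t[-length(t)]) / 2
  ok <- dl > 0 & is.finite(dl)
  alpha2 <- if (sum(ok) >= 2) {
    sl <- stats::coef(stats::lm(log(dl[ok]) ~ mid[ok]))[[2]]
    max(-sl, 1e-4)
  } else 0.05
  alpha1 <- max(alpha2 * max(logc), 1e-4)
  lnK <- alpha1 / alpha2
  lnC0 <- lnK - (lnK - logc[1]) * exp(alpha2 * t[1])
  list(alpha1 = alpha1, alpha2 = alpha2, lnC0 = max(lnC0, 0))
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("<gompertz_fit> Gompertz growth fit on log-counts\n")
  cat(sprintf("  alpha1 = %.5g, alpha2 = %.5g (plateau %.4g cells)\n",
              x$alpha1_hat, x$alpha2_hat, exp(x$alpha1_hat / x$alpha2_hat)))
  cat(sprintf("  C0 = %.5g (%s), n = %d, residual sigma (log scale) = %.3g\n",
              x$C0, if (x$C0_estimated) "estimated" else "fixed",
              x$nobs, x$sigma))
  if (x$wide_ci) {
    cat("  warning: unidentifiable fit, confidence ranges are unbounded\n")
  }
  invisible(x)
}

#' Predict counts from a Gompertz fit
#'
#' @param object A `gompertz_fit`.
#' @param t Times in \eqn{\Delta t} units.
#' @param ... Unused.
#' @return Predicted cell counts.
#' @export
predict.gompertz_fit <- function(object, t, ...) {
  gompertz_closed_form(t, object$C0, object$alpha1_hat, object$alpha2_hat)
}
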