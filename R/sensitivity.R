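#' Default sampling ranges for the global sensitivity analysis
#'
#' Builds the per-parameter `[lower, upper]` bounds over which the Latin
#' hypercube samples the model. Every kinetic rate and threshold
#' (`alpha1..alpha11`, `h`, `k1..k3`, `M`) varies by +/- `span` (default
#' 50%) around its nominal value; the treatment doses `p` and `q` vary
#' over `dose_span` times nominal (default 0.25x to 2x, the clinically
#' interesting dose-reduction question); and, when a [fit_gompertz()]
#' object is supplied, `alpha1` and `alpha2` instead take the confidence
#' ranges estimated from the growth-curve fit, so the sampled tumours span
#' the growth kinetics compatible with the measurements. A `dummy` row on
#' `[0, 1]` is appended: it is sampled like any other parameter but never
#' enters the model, providing the negative control against which PRCC
#' significance is judged. `C0` and `tau` are held fixed.
#'
#' @param params A [model_params()] object with the nominal values.
#' @param gompertz_fit Optional `gompertz_fit`; its `alpha1`/`alpha2`
#'   confidence ranges replace the +/- `span` defaults.
#' @param span Half-width of the relative variation for rates/thresholds.
#' @param dose_span Length-2 multiplier range for the doses `p` and `q`.
#' @param include_dummy Append the dummy control row? Default `TRUE`.
#' @return A tibble with columns `parameter`, `lower`, `upper`; only the
#'   listed parameters are varied.
#' @export
default_ranges <- function(params, gompertz_fit = NULL, span = 0.5,
                           dose_span = c(0.25, 2), include_dummy = TRUE) {
  validate_params(params)
  varied <- c(paste0("alpha", 1:11), "h", "k1", "k2", "k3", "M")
  vals <- unlist(params[varied])
  rng <- tibble::tibble(
    parameter = varied,
    lower = unname(vals * (1 - span)),
    upper = unname(vals * (1 + span))
  )
  if (!is.null(gompertz_fit)) {
    if (!inherits(gompertz_fit, "gompertz_fit")) {
      stop("gompertz_fit must be a gompertz_fit object", call. = FALSE)
    }
    cf <- gompertz_fit$coefficients
    for (a in c("alpha1", "alpha2")) {
      row <- cf[cf$term == a, ]
      lo <- unname(max(row$conf.low, 1e-6))
      hi <- unname(row$conf.high)
      if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
        stop("gompertz fit confidence ranges are unusable for ", a,
             call. = FALSE)
      }
      rng$lower[rng$parameter == a] <- lo
      rng$upper[rng$parameter == a] <- hi
    }
  }
  doses <- tibble::tibble(
    parameter = c("p", "q"),
    lower = dose_span[1] * c(params$p, params$q),
    upper = dose_span[2] * c(params$p, params$q)
  )
  rng <- dplyr::bind_rows(rng, doses)
  if (include_dummy) {
    rng <- dplyr::bind_rows(
      rng, tibble::tibble(parameter = "dummy", lower = 0, upper = 1))
  }
  if (any(rng$lower >= rng$upper)) {
    stop("every varied parameter needs lower < upper", call. = FALSE)
  }
  rng
}

#' Latin hypercube sample of a parameter space
#'
#' Draws `n` points from the box defined by `ranges`, stratified so that
#' each parameter column contains exactly one value in each of its `n`
#' equal-probability strata (marginals are uniform on each range, the
#' standard choice for LHS-PRCC analyses), with strata paired by
#' independent random permutations.
#'
#' @param ranges A tibble with columns `parameter`, `lower`, `upper`
#'   (see [default_ranges()]).
#' @param n Number of samples, at least 2.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n` x `k` tibble, one column per parameter.
#' @examples
#' rng <- default_ranges(model_params())
#' X <- lhs_sample(rng, 10, seed = 1)
#' @export
lhs_sample <- function(ranges, n, seed = NULL) {
  if (!is.data.frame(ranges) ||
      !all(c("parameter", "lower", "upper") %in% names(ranges))) {
    stop("ranges must have columns parameter, lower, upper", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("sample-size error: n must be at least 2", call. = FALSE)
  }
  if (any(ranges$lower >= ranges$upper)) {
    stop("every range needs lower < upper", call. = FALSE)
  }
  n <- as.integer(n)
  k <- nrow(ranges)
  U <- if (is.null(seed)) {
    lhs::randomLHS(n, k)
  } else {
    withr::with_seed(seed, lhs::randomLHS(n, k))
  }
  X <- sweep(U, 2, ranges$upper - ranges$lower, `*`)
  X <- sweep(X, 2, ranges$lower, `+`)
  colnames(X) <- ranges$parameter
  tibble::as_tibble(X)
}

#' Partial rank correlation coefficients
#'
#' For each input parameter, ranks all inputs and the output (average ranks
#' on ties), removes from both the parameter's ranks and the output's ranks
#' the linear effect of the other parameters' ranks, and correlates the two
#' residual vectors. The result is insensitive to any strictly monotone
#' transformation of inputs or output. P-values come from the t statistic
#' `r * sqrt(df / (1 - r^2))` with `df = n - 2 - (k - 1)` degrees of
#' freedom (two-sided).
#'
#' @param samples An `n` x `k` data frame or matrix of sampled inputs.
#' @param output Numeric vector of length `n`, the model output.
#' @return A tibble with columns `parameter`, `prcc`, `statistic`, `df`,
#'   `p_value`.
#' @examples
#' X <- lhs_sample(default_ranges(model_params()), 100, seed = 2)
#' prcc(X, X$alpha3 + rnorm(100, sd = 1e-9))  # alpha3 drives the output
#' @export
prcc <- function(samples, output) {
  X <- as.matrix(samples)
  n <- nrow(X)
  k <- ncol(X)
  if (length(output) != n) {
    stop("output must have one value per sample row", call. = FALSE)
  }
  if (n <= k + 2) {
    stop(sprintf("insufficient samples: need n > k + 2 (n = %d, k = %d)",
                 n, k), call. = FALSE)
  }
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate input: constant sample column", call. = FALSE)
  }
  if (stats::sd(output) == 0) {
    stop("degenerate input: constant output", call. = FALSE)
  }
  R <- apply(X, 2, rank)
  ry <- rank(output)
  df <- n - 2 - (k - 1)
  r <- numeric(k)
  for (j in seq_len(k)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    res <- stats::lm.fit(Z, cbind(R[, j], ry))$residuals
    # if the covariates explain either side perfectly there is no residual
    # variation left to correlate: the partial correlation is 0
    if (stats::sd(res[, 1]) < 1e-10 * n || stats::sd(res[, 2]) < 1e-10 * n) {
      r[j] <- 0
    } else {
      r[j] <- stats::cor(res[, 1], res[, 2])
    }
  }
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  pval[r^2 >= 1] <- 0
  tibble::tibble(
    parameter = colnames(X),
    prcc = r,
    statistic = tstat,
    df = df,
    p_value = pval
  )
}

#' Time-resolved PRCC sensitivity of the melanoma burden
#'
#' Runs one model integration per Latin-hypercube sample (the `dummy`
#' column, if present, is drawn but never enters the model), reads the
#' melanoma cell count `C` at each output time, and computes PRCCs of every
#' sampled parameter against `C(t)` per time point, with pointwise
#' significance at `p < alpha` (default 0.01, matching the significance
#' bands drawn around the PRCC time plots). Injection doses `p` and `q`
#' flow into the sampled scenario's bolus, so their sensitivity is the
#' sensitivity to the administered treatment quantities.
#'
#' Failed integrations are dropped with a warning; if more than 10% of the
#' sampled rows fail the analysis aborts.
#'
#' @param params Nominal [model_params()].
#' @param ranges Sampling ranges (default [default_ranges()] of `params`).
#' @param n Number of LHS samples (default 1000; 200 gives a quick but
#'   stable sign picture).
#' @param scenario Treatment arm to simulate (default `"combined"`).
#' @param output_times Times (in \eqn{\Delta t} units) at which PRCCs are
#'   computed; default every 3 steps (daily) from 3 to 99.
#' @param seed Optional integer seed.
#' @param hstep,horizon Passed to [integrate_model()].
#' @param alpha Pointwise significance level (default 0.01).
#' @param output Which population to correlate against (default `"C"`).
#' @return A `prcc_timecourse`: a tibble with columns `time_dt`,
#'   `time_days`, `parameter`, `prcc`, `p_value`, `significant`, carrying
#'   the ranges, sample size, failure count and seed as attributes.
#' @export
prcc_timecourse <- function(params, ranges = NULL, n = 1000,
                            scenario = "combined",
                            output_times = seq(3, 99, by = 3),
                            seed = NULL, hstep = NULL, horizon = 100,
                            alpha = 0.01, output = "C") {
  validate_params(params)
  if (is.null(ranges)) ranges <- default_ranges(params)
  if (!output %in% state_vars()) {
    stop("output must be one of: ", paste(state_vars(), collapse = ", "),
         call. = FALSE)
  }
  if (any(output_times < 0) || any(output_times > horizon)) {
    stop("output_times must lie within [0, horizon]", call. = FALSE)
  }
  X <- lhs_sample(ranges, n, seed = seed)
  model_pars <- setdiff(names(X), "dummy")
  unknown <- setdiff(model_pars, param_field_names())
  if (length(unknown) > 0) {
    stop("ranges refer to unknown model parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  nt <- length(output_times)
  out_mat <- matrix(NA_real_, nrow = n, ncol = nt)
  failures <- character()
  for (i in seq_len(n)) {
    prm <- params
    for (nm in model_pars) prm[[nm]] <- X[[nm]][i]
    res <- tryCatch({
      validate_params(prm)
      traj <- run_scenario(prm, scenario, horizon = horizon, hstep = hstep)
      stats::approx(traj$time_dt, traj[[output]], xout = output_times)$y
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("row %d: %s", i, res))
    } else {
      out_mat[i, ] <- res
    }
  }
  kept <- which(stats::complete.cases(out_mat))
  n_failed <- n - length(kept)
  if (n_failed > 0.1 * n) {
    stop(sprintf("aborting: %d of %d sampled integrations failed (>10%%); first: %s",
                 n_failed, n, failures[1]), call. = FALSE)
  }
  if (n_failed > 0) {
    warning(sprintf("%d of %d sampled integrations failed and were dropped",
                    n_failed, n), call. = FALSE)
  }
  Xk <- X[kept, , drop = FALSE]
  per_time <- purrr::map(seq_len(nt), function(ti) {
    y <- out_mat[kept, ti]
    tab <- if (stats::sd(y) == 0) {
      tibble::tibble(parameter = names(X), prcc = NA_real_,
                     statistic = NA_real_, df = NA_integer_,
                     p_value = NA_real_)
    } else {
      prcc(Xk, y)
    }
    tab$time_dt <- output_times[ti]
    tab
  })
  tbl <- dplyr::bind_rows(per_time) |>
    dplyr::mutate(
      time_days = dt_to_days(.data$time_dt, params$dt_hours),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) |>
    dplyr::select("time_dt", "time_days", "parameter", "prcc",
                  "p_value", "significant")
  structure(tbl,
            ranges = ranges, n_samples = n, n_failed = n_failed,
            seed = seed, alpha = alpha, scenario = scenario,
            output = output,
            class = c("prcc_timecourse", class(tbl)))
}

#' @export
print.prcc_timecourse <- function(x, ...) {
  cat(sprintf("<prcc_timecourse> %s scenario, output %s: %d parameters x %d time points\n",
              attr(x, "scenario"), attr(x, "output"),
              length(unique(x$parameter)), length(unique(x$time_dt))))
  cat(sprintf("  n = %d LHS samples (%d failed), pointwise significance at p < %g\n",
              attr(x, "n_samples"), attr(x, "n_failed"), attr(x, "alpha")))
  NextMethod()
}
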