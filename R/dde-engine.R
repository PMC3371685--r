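#' Injection schedules
#'
#' A treatment schedule is a tibble of impulsive injection events, one row
#' per bolus, with columns `time_dt` (injection time in \eqn{\Delta t}
#' units), `dE` (activated CTLs added to the injection-point compartment)
#' and `dAb` (antibodies added). Boluses are applied as instantaneous state
#' jumps by [integrate_model()].
#'
#' @param time_dt Injection times, \eqn{\Delta t} units (non-negative).
#' @param dE Cells added to `E` at each time.
#' @param dAb Antibodies added to `Ab` at each time.
#' @return A tibble with columns `time_dt`, `dE`, `dAb`.
#' @examples
#' injection_schedule(9, dE = 760000, dAb = 1e6) # day-3 combined bolus
#' @export
injection_schedule <- function(time_dt = numeric(), dE = 0, dAb = 0) {
  ev <- tibble::tibble(time_dt = as.numeric(time_dt),
                       dE = as.numeric(dE),
                       dAb = as.numeric(dAb))
  if (nrow(ev) > 0 && (any(ev$time_dt < 0) || any(ev$dE < 0) ||
                       any(ev$dAb < 0))) {
    stop("injection events need time_dt >= 0 and non-negative doses",
         call. = FALSE)
  }
  ev
}

#' Apply a bolus injection to a state
#'
#' Adds the event's dose to the injection-point populations: `E` gains
#' `dE`, `Ab` gains `dAb`, every other component is untouched.
#'
#' @param state Named state vector (see [initial_state()]).
#' @param event A one-row data frame or list with elements `dE` and `dAb`.
#' @return The updated state vector.
#' @export
apply_impulse <- function(state, event) {
  state <- as_state(state)
  dE <- as.numeric(event$dE)
  dAb <- as.numeric(event$dAb)
  if (length(dE) != 1 || length(dAb) != 1 || dE < 0 || dAb < 0) {
    stop("event doses must be single non-negative numbers", call. = FALSE)
  }
  state[["E"]] <- state[["E"]] + dE
  state[["Ab"]] <- state[["Ab"]] + dAb
  state
}

#' Look up the model state at an earlier time
#'
#' Dense history access used for the delayed terms `alpha11 * E(t - tau)`
#' and `alpha11 * Ab(t - tau)`. Query times before the start of the
#' experiment return the pre-history state, which equals the initial
#' conditions (nothing has been injected yet, the skin holds only the naive
#' pool and the inoculated tumour). Queries on a stored grid node return
#' that node's state verbatim; off-node queries are linearly interpolated.
#'
#' @param trajectory A `melimm_trajectory` as returned by
#'   [integrate_model()].
#' @param t_query Query time in \eqn{\Delta t} units; must not exceed the
#'   last stored time.
#' @return Named state vector at `t_query`.
#' @export
history_lookup <- function(trajectory, t_query) {
  if (!inherits(trajectory, "melimm_trajectory")) {
    stop("trajectory must be a melimm_trajectory", call. = FALSE)
  }
  if (length(t_query) != 1 || !is.finite(t_query)) {
    stop("t_query must be a single finite time", call. = FALSE)
  }
  params <- attr(trajectory, "params")
  if (t_query < 0) return(initial_state(params))
  tmax <- trajectory$time_dt[nrow(trajectory)]
  if (t_query > tmax + 1e-9) {
    stop(sprintf("lookup-ahead: t_query = %g is beyond the stored history (%g)",
                 t_query, tmax), call. = FALSE)
  }
  out_step <- attr(trajectory, "out_step") %||% attr(trajectory, "hstep")
  fi <- t_query / out_step
  i0 <- floor(fi + 1e-9)
  w <- fi - i0
  Y <- as.matrix(trajectory[, state_vars()])
  s <- if (w < 1e-9 || i0 + 2 > nrow(Y)) {
    Y[i0 + 1, ]
  } else {
    (1 - w) * Y[i0 + 1, ] + w * Y[i0 + 2, ]
  }
  names(s) <- state_vars()
  s
}

#' Integrate the melanoma--immune DDE system
#'
#' Advances the seven-population model from its initial conditions with a
#' classical fixed-step 4th-order Runge--Kutta scheme organised as a method
#' of steps: the grid step `hstep` must divide the delay `tau` (and every
#' injection time), so delayed values at grid nodes are read directly from
#' the stored history; values needed at Runge--Kutta half-stages are
#' linearly interpolated between the two bracketing nodes. Injection
#' boluses are instantaneous state jumps applied at their (grid-aligned)
#' event time, before the step departing that node, so both the jump and
#' its delayed echo at `time + tau` land on grid nodes and no step
#' straddles a discontinuity. The inner loop is compiled (C++).
#'
#' **Step size.** Once injected CTLs reach the skin and start killing
#' tumour cells, the antigen equation is stiff: released antigen is cleared
#' by naive-CTL activation at rate `alpha6 * N`, about `2e4` per
#' \eqn{\Delta t} at the default calibration, far above every other rate in
#' the system. An explicit scheme is only stable while
#' `hstep * alpha6 * N` stays inside the RK4 stability interval, so treated
#' runs need steps of order `1e-4` \eqn{\Delta t}. With `hstep = NULL`
#' (default) the step is chosen automatically: `~1.4 / (alpha6 * M)` when
#' the schedule injects CTLs (rounded so it divides `tau`), and 0.05 for
#' schedules that cannot produce antigen (no CTL bolus), where the system
#' is non-stiff. Pass an explicit `hstep` to override.
#'
#' After every step each component is floored at zero. Under the default
#' calibration the floor only ever engages as the tumour is driven to
#' extinction; the number of clamped entries is recorded in the
#' `clamp_count` attribute of the result.
#'
#' @param params A [model_params()] object.
#' @param schedule An [injection_schedule()] tibble, or `NULL` for an
#'   untreated run.
#' @param horizon Integration horizon in \eqn{\Delta t} units (default 100,
#'   i.e. about 33 days at 8-hour steps).
#' @param hstep Integration step in \eqn{\Delta t} units; must divide
#'   `tau`, `horizon` and every event time. `NULL` (default) selects a
#'   stable step automatically (see Details).
#' @param out_step Spacing of the stored output grid, a multiple of
#'   `hstep`; default about 0.1 \eqn{\Delta t} (or `hstep` if coarser).
#' @return A `melimm_trajectory`: a tibble with columns `time_dt`,
#'   `time_days`, `E`, `Ab`, `Es`, `As`, `N`, `C`, `A`, one row per stored
#'   grid node, carrying the parameters, schedule, step sizes and clamp
#'   count as attributes.
#' @examples
#' params <- model_params()
#' untreated <- integrate_model(params, horizon = 30)
#' tail(untreated, 3)
#' @export
integrate_model <- function(params, schedule = NULL, horizon = 100,
                            hstep = NULL, out_step = NULL) {
  validate_params(params)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 0) {
    stop("horizon must be a single non-negative number", call. = FALSE)
  }
  if (is.null(schedule)) schedule <- injection_schedule()
  if (!all(c("time_dt", "dE", "dAb") %in% names(schedule))) {
    stop("schedule must have columns time_dt, dE, dAb", call. = FALSE)
  }
  schedule <- schedule[order(schedule$time_dt), , drop = FALSE]
  schedule <- schedule[schedule$time_dt <= horizon + 1e-9, , drop = FALSE]

  if (is.null(hstep)) {
    hstep <- auto_hstep(params, schedule)
  }
  if (!is.numeric(hstep) || length(hstep) != 1 || hstep <= 0) {
    stop("hstep must be a single positive number", call. = FALSE)
  }
  grid_index <- function(t, what) {
    k <- t / hstep
    if (any(abs(k - round(k)) > 1e-6 * pmax(1, abs(k)))) {
      stop(sprintf("grid-alignment error: hstep = %g must divide %s",
                   hstep, what), call. = FALSE)
    }
    as.integer(round(k))
  }
  tau_steps <- grid_index(params$tau, "tau")
  n_steps <- grid_index(horizon, "the horizon")
  ev_steps <- if (nrow(schedule) > 0) {
    grid_index(schedule$time_dt, "every event time")
  } else integer()

  if (is.null(out_step)) out_step <- 0.1
  thin <- max(1L, as.integer(round(out_step / hstep)))
  if (n_steps > 0) {
    while (n_steps %% thin != 0L) thin <- thin - 1L
  } else thin <- 1L
  out_step <- thin * hstep

  y0 <- unname(initial_state(params))
  avec <- unlist(params[c(paste0("alpha", 1:11), "h", "k1", "k2", "k3", "M")])
  core <- integrate_rk4_core(y0, avec, hstep, n_steps, tau_steps, thin,
                             ev_steps, schedule$dE, schedule$dAb)
  Y <- core$states
  colnames(Y) <- state_vars()
  times <- seq(0, by = out_step, length.out = nrow(Y))
  out <- dplyr::bind_cols(
    tibble::tibble(time_dt = times,
                   time_days = dt_to_days(times, params$dt_hours)),
    tibble::as_tibble(Y)
  )
  new_trajectory(out, params = params, events = schedule, hstep = hstep,
                 out_step = out_step, clamp_count = core$clamp_count)
}

# Stable step for the explicit RK4 scheme. Stiffness enters through the
# antigen-clearance rate alpha6 * N (bounded by alpha6 * M up to small
# homeostasis overshoot); it is only excited when injected CTLs can reach
# the skin and kill, i.e. when some bolus carries dE > 0. 1.4 keeps
# hstep * lambda well inside the RK4 real stability interval (~2.79).
auto_hstep <- function(params, schedule) {
  stiff <- nrow(schedule) > 0 && any(schedule$dE > 0)
  h_target <- if (stiff) {
    1.4 / (params$alpha6 * params$M * 1.05 + params$alpha5)
  } else 0.05
  if (params$tau > 0) {
    # steps-per-tau rounded up to a multiple of 10, so the default output
    # grid (tau / 10) is an exact subgrid and grid-aligned events stay on it
    m <- 10 * ceiling(params$tau / h_target / 10)
    params$tau / m
  } else {
    h_target
  }
}

new_trajectory <- function(tbl, params, events, hstep, out_step = hstep,
                           clamp_count = 0L, scenario = NA_character_) {
  structure(tbl,
            params = params, events = events, hstep = hstep,
            out_step = out_step, clamp_count = clamp_count,
            scenario = scenario,
            class = c("melimm_trajectory", class(tbl)))
}

#' Extract the state at a given day
#'
#' Convenience accessor: linearly interpolates every population of a
#' trajectory at the requested days.
#'
#' @param trajectory A `melimm_trajectory`.
#' @param days Days at which to read the state (within the horizon).
#' @return A tibble with one row per requested day.
#' @export
state_at_day <- function(trajectory, days) {
  params <- attr(trajectory, "params")
  t_dt <- days_to_dt(days, params$dt_hours)
  tmax <- max(trajectory$time_dt)
  if (any(t_dt < 0) || any(t_dt > tmax + 1e-9)) {
    stop(sprintf("requested day outside the simulated horizon (0..%g days)",
                 dt_to_days(tmax, params$dt_hours)), call. = FALSE)
  }
  cols <- lapply(state_vars(), function(v) {
    stats::approx(trajectory$time_dt, trajectory[[v]], xout = t_dt)$y
  })
  names(cols) <- state_vars()
  dplyr::bind_cols(tibble::tibble(day = days, time_dt = t_dt),
                   tibble::as_tibble(cols))
}

#' Write a trajectory to a tidy CSV file
#'
#' Columns are `time_dt`, `time_days`, the seven populations, and the
#' scenario label.
#'
#' @param trajectory A `melimm_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)[, c("time_dt", "time_days", state_vars())]
  scen <- attr(trajectory, "scenario")
  df$scenario <- if ("scenario" %in% names(trajectory)) {
    trajectory$scenario
  } else if (!is.na(scen)) scen else "custom"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.melimm_trajectory <- function(x, ...) {
  scen <- attr(x, "scenario")
  cat(sprintf("<melimm_trajectory>%s %d nodes (every %g dt), hstep = %g dt, horizon = %g dt (%.1f days)\n",
              if (!is.na(scen)) paste0(" [", scen, "]") else "",
              nrow(x), attr(x, "out_step"), attr(x, "hstep"),
              max(x$time_dt), max(x$time_days)))
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev) > 0) {
    cat(sprintf("  %d injection event(s) at t = %s dt\n", nrow(ev),
                paste(ev$time_dt, collapse = ", ")))
  }
  if (isTRUE(attr(x, "clamp_count") > 0)) {
    cat(sprintf("  zero-floor clamp engaged %d time(s)\n",
                attr(x, "clamp_count")))
  }
  NextMethod()
}
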