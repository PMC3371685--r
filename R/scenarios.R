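#' Vaccination protocols
#'
#' The four in vivo treatment arms reproduced by the model. Every treated
#' arm receives one single bolus at day 3 (= 9 \eqn{\Delta t} at 8-hour
#' steps); the doses come from the parameter set (`p` activated OT1 CTLs,
#' `q` anti-CD137 antibodies).
#'
#' * `untreated` - control, empty schedule;
#' * `ot1_only`  - activated OT1 CTLs alone (`dE = p`);
#' * `ab_only`   - anti-CD137 antibodies alone (`dAb = q`);
#' * `combined`  - both (`dE = p`, `dAb = q`).
#'
#' @return `scenario_names()` returns the four scenario labels.
#' @export
scenario_names <- function() c("untreated", "ot1_only", "ab_only", "combined")

#' @rdname scenario_names
#' @param name One of [scenario_names()].
#' @param params A [model_params()] object supplying the doses.
#' @param day Injection day (default 3, the in vivo protocol).
#' @return `build_schedule()` returns a list with elements `name` and
#'   `schedule` (an [injection_schedule()] tibble).
#' @examples
#' build_schedule("combined", model_params())
#' @export
build_schedule <- function(name, params, day = 3) {
  validate_params(params)
  t_inj <- days_to_dt(day, params$dt_hours)
  schedule <- switch(name,
    untreated = injection_schedule(),
    ot1_only = injection_schedule(t_inj, dE = params$p, dAb = 0),
    ab_only = injection_schedule(t_inj, dE = 0, dAb = params$q),
    combined = injection_schedule(t_inj, dE = params$p, dAb = params$q),
    stop(sprintf("unknown scenario '%s'; expected one of: %s", name,
                 paste(scenario_names(), collapse = ", ")), call. = FALSE)
  )
  structure(list(name = name, schedule = schedule),
            class = "melimm_scenario")
}

#' Run one treatment scenario
#'
#' Builds the scenario's injection schedule and integrates the model.
#'
#' @inheritParams build_schedule
#' @inheritParams integrate_model
#' @return A `melimm_trajectory` with an extra `scenario` column.
#' @examples
#' traj <- run_scenario(model_params(), "combined", horizon = 30)
#' @export
run_scenario <- function(params, name, horizon = 100, hstep = NULL, day = 3) {
  scen <- build_schedule(name, params, day = day)
  traj <- tryCatch(
    integrate_model(params, scen$schedule, horizon = horizon, hstep = hstep),
    error = function(e) {
      stop(sprintf("scenario '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    }
  )
  traj$scenario <- name
  attr(traj, "scenario") <- name
  traj
}

#' Run all four treatment scenarios on a shared grid
#'
#' @inheritParams run_scenario
#' @param names Scenarios to run; defaults to all four arms.
#' @return A tibble stacking the four trajectories, distinguished by the
#'   `scenario` column; the parameter set and step size ride along as
#'   attributes.
#' @examples
#' runs <- run_scenarios(model_params(), horizon = 30)
#' dplyr::count(runs, scenario)
#' @export
run_scenarios <- function(params, names = scenario_names(), horizon = 100,
                          hstep = NULL, day = 3) {
  trajs <- purrr::map(names, function(nm) {
    tibble::as_tibble(run_scenario(params, nm, horizon = horizon,
                                   hstep = hstep, day = day))
  })
  out <- dplyr::bind_rows(trajs)
  structure(out, params = params, hstep = hstep,
            class = c("melimm_scenarios", class(out)))
}
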