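params <- model_params()

test_that("impulses add to the injection-point populations only", {
  s <- initial_state(params)
  ev <- injection_schedule(9, dE = 760000, dAb = 1e6)
  s2 <- apply_impulse(s, ev[1, ])
  expect_equal(s2[["E"]], 760000)
  expect_equal(s2[["Ab"]], 1e6)
  expect_equal(s2[c("Es", "As", "N", "C", "A")],
               s[c("Es", "As", "N", "C", "A")])
  expect_equal(apply_impulse(s, list(dE = 0, dAb = 0)), s)
  expect_error(injection_schedule(9, dE = -1), "non-negative")
})

test_that("history lookup honours pre-history, nodes and bounds", {
  tr <- integrate_model(params, horizon = 5, hstep = 0.1)
  expect_equal(history_lookup(tr, -0.5), initial_state(params))
  expect_equal(history_lookup(tr, 0), initial_state(params))
  node <- history_lookup(tr, 2.5)
  row <- tr[tr$time_dt == 2.5, ]
  expect_equal(node[["C"]], row$C)
  expect_equal(node[["N"]], row$N)
  expect_error(history_lookup(tr, 6), "lookup-ahead")
})

test_that("untreated run: only the tumour moves and it follows Gompertz", {
  tr <- integrate_model(params, horizon = 100, hstep = 0.1)
  expect_identical(nrow(tr), 1001L)
  # conservation: all treatment-derived populations stay exactly zero
  for (v in c("E", "Ab", "Es", "As", "A")) {
    expect_identical(unique(tr[[v]]), 0)
  }
  expect_identical(unique(tr$N), params$M)
  cf <- gompertz_closed_form(tr$time_dt, params$C0, params$alpha1,
                             params$alpha2)
  expect_lt(max(abs(tr$C - cf) / cf), 1e-3)
  # initial conditions stored verbatim
  expect_equal(unlist(tr[1, c("E", "Ab", "Es", "As", "N", "C", "A")]),
               initial_state(params))
})

test_that("non-negativity holds at every stored node in all arms", {
  for (nm in scenario_names()) {
    tr <- run_scenario(params, nm, horizon = 40)
    expect_true(all(as.matrix(tr[, c("E", "Ab", "Es", "As", "N", "C",
                                     "A")]) >= 0))
    expect_true(all(diff(tr$time_dt) > 0))
    expect_equal(unique(round(diff(tr$time_dt), 12)),
                 attr(tr, "out_step"))
  }
})

test_that("grid misalignment and bad inputs are rejected", {
  expect_error(integrate_model(params, horizon = 10, hstep = 0.3),
               "grid-alignment")
  sch <- injection_schedule(9.05, dE = 1000)
  expect_error(integrate_model(params, sch, horizon = 10, hstep = 0.1),
               "grid-alignment")
  expect_error(integrate_model(params, horizon = -5), "horizon")
  expect_error(integrate_model(params, horizon = 10, hstep = -0.1), "hstep")
})

test_that("between impulses E follows its exact exponential decay", {
  sch <- injection_schedule(9, dE = params$p, dAb = params$q)
  tr <- integrate_model(params, sch, horizon = 10, hstep = 0.05)
  lambda <- params$alpha11 + params$alpha8
  post <- tr[tr$time_dt >= 9, ]
  expect_lt(max(abs(post$E - params$p * exp(-lambda * (post$time_dt - 9))) /
                  (params$p * exp(-lambda * (post$time_dt - 9)))), 1e-6)
  expect_true(all(tr$E[tr$time_dt < 9] == 0))
  # and on the full stiff run with the automatic step
  tr2 <- run_scenario(params, "combined")
  post2 <- tr2[tr2$time_dt >= 9, ]
  ref <- params$p * exp(-lambda * (post2$time_dt - 9))
  expect_lt(max(abs(post2$E - ref) / ref), 1e-6)
})

test_that("first-order brute-force stepping reproduces the solution across the injection", {
  sch <- injection_schedule(9, dE = params$p, dAb = params$q)
  # window [0, 10]: contains the bolus; the delayed migration (and with it
  # the stiff antigen flux) only begins at 9 + tau = 10
  oracle <- oracle_euler_dde(params, sch, horizon = 10, h = 1e-3)
  tr <- integrate_model(params, sch, horizon = 10, hstep = 0.1)
  idx <- match(round(tr$time_dt, 9), round(oracle$times, 9))
  expect_false(anyNA(idx))
  for (v in c("E", "Ab", "Es", "As", "N", "C", "A")) {
    floor_v <- max(1, 1e-9 * max(tr[[v]]))
    expect_lt(max(rel_err(tr[[v]], oracle$states[idx, v], floor_v)), 1e-3)
  }
})

test_that("the solution converges under step refinement", {
  a <- run_scenario(params, "combined")
  b <- run_scenario(params, "combined", hstep = attr(a, "hstep") / 4)
  expect_identical(a$time_dt, b$time_dt)
  for (v in c("E", "Ab", "Es", "As", "N", "C", "A")) {
    expect_lt(max(rel_err(a[[v]], b[[v]])), 1e-3)
  }
})

test_that("the integrator agrees with an adaptive stiff DDE solver", {
  # independent cross-check of the full (stiff) combined trajectory
  p <- params
  y0 <- initial_state(p)
  derivs <- function(t, y, parms) {
    yd <- if (t - p$tau < 0) y0 else deSolve::lagvalue(t - p$tau)
    names(yd) <- names(y0)
    list(unname(melanoma_rhs(pmax(y, 0), pmax(yd, 0), p)))
  }
  ev <- data.frame(var = c("E", "Ab"), time = c(9, 9),
                   value = c(p$p, p$q), method = "add")
  times <- seq(0, 100, by = 1)
  sol <- deSolve::dede(y = y0, times = times, func = derivs, parms = NULL,
                       events = list(data = ev), atol = 1e-6, rtol = 1e-8,
                       maxsteps = 100000)
  tr <- run_scenario(p, "combined")
  for (v in c("Es", "As", "N", "C")) {
    mine <- stats::approx(tr$time_dt, tr[[v]], xout = times)$y
    floor_v <- 1e-4 * max(mine)
    expect_lt(max(rel_err(sol[, v], mine, floor_v)), 5e-3)
  }
})

test_that("trajectories write out as tidy CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- run_scenario(params, "untreated", horizon = 10)
  write_trajectory(tr, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("time_dt", "time_days", "E", "Ab", "Es",
                                "As", "N", "C", "A", "scenario"))
  expect_identical(unique(df$scenario), "untreated")
  expect_equal(df$C, tr$C)
})

test_that("states can be read at arbitrary days within the horizon", {
  tr <- run_scenario(params, "untreated", horizon = 30)
  st <- state_at_day(tr, c(0, 5.5, 10))
  expect_equal(st$C[1], params$C0)
  expect_error(state_at_day(tr, 40), "horizon")
})
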