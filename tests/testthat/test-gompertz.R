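params <- model_params()

test_that("closed form solves the Gompertz law", {
  expect_equal(gompertz_closed_form(0, params$C0, params$alpha1,
                                    params$alpha2), params$C0)
  plateau <- exp(params$alpha1 / params$alpha2)
  expect_equal(gompertz_closed_form(1e6, params$C0, params$alpha1,
                                    params$alpha2), plateau,
               tolerance = 1e-12)
  # independent fine-step integration of the scalar ODE
  num <- oracle_gompertz_ode(params$C0, params$alpha1, params$alpha2,
                             t_end = 50, h = 1e-3)
  cf <- gompertz_closed_form(50, params$C0, params$alpha1, params$alpha2)
  expect_lt(abs(num - cf) / cf, 1e-8)
  expect_error(gompertz_closed_form(5, 0.5, 0.2, 0.01), "C0")
  expect_error(gompertz_closed_form(-1, 10, 0.2, 0.01), "non-negative")
})

test_that("noiseless measurements recover the published growth rates", {
  times <- seq(10, 100, by = 10)
  df <- data.frame(
    time_dt = times,
    cells = gompertz_closed_form(times, params$C0, params$alpha1,
                                 params$alpha2)
  )
  fit <- fit_gompertz(df)
  expect_lt(abs(fit$alpha1_hat - 0.2165) / 0.2165, 1e-6)
  expect_lt(abs(fit$alpha2_hat - 0.01269) / 0.01269, 1e-6)
  expect_lt(abs(fit$C0 - params$C0) / params$C0, 1e-5)
  co <- fit$coefficients
  expect_true(all(co$conf.low <= co$estimate & co$estimate <= co$conf.high))
  # with the initial burden supplied instead of estimated
  fit2 <- fit_gompertz(df, C0 = params$C0)
  expect_lt(abs(fit2$alpha1_hat - 0.2165) / 0.2165, 1e-6)
  expect_lt(abs(fit2$alpha2_hat - 0.01269) / 0.01269, 1e-6)
})

test_that("estimates stay close under multiplicative measurement noise", {
  times <- seq(10, 100, length.out = 10)
  truth <- gompertz_closed_form(times, params$C0, params$alpha1,
                                params$alpha2)
  set.seed(2024)
  fit <- fit_gompertz(
    data.frame(time_dt = times, cells = truth * exp(0.05 * rnorm(10))),
    C0 = params$C0
  )
  expect_lt(abs(fit$alpha1_hat - params$alpha1) / params$alpha1, 0.10)
  expect_lt(abs(fit$alpha2_hat - params$alpha2) / params$alpha2, 0.15)
})

test_that("fit-generate is an approximate identity over many replicates", {
  times <- seq(10, 100, length.out = 10)
  truth <- gompertz_closed_form(times, params$C0, params$alpha1,
                                params$alpha2)
  set.seed(77)
  errs <- t(replicate(100, {
    cts <- truth * exp(0.05 * rnorm(10))
    f <- fit_gompertz(data.frame(time_dt = times, cells = cts),
                      C0 = params$C0)
    c(abs(f$alpha1_hat - params$alpha1) / params$alpha1,
      abs(f$alpha2_hat - params$alpha2) / params$alpha2)
  }))
  expect_lt(stats::median(errs[, 1]), 0.05)
  expect_lt(stats::median(errs[, 2]), 0.05)
})

test_that("degenerate and insufficient data are flagged", {
  expect_error(fit_gompertz(data.frame(time_dt = c(1, 2), cells = c(5, 6))),
               "insufficient")
  expect_error(fit_gompertz(data.frame(time_dt = 1:5, cells = rep(0.5, 5))),
               "counts")
  # all observations at the plateau: individual rates unidentifiable
  plateau <- exp(params$alpha1 / params$alpha2)
  res <- tryCatch(
    fit_gompertz(data.frame(time_dt = seq(10, 60, 10),
                            cells = rep(plateau, 6))),
    error = function(e) e
  )
  expect_true(inherits(res, "error") || isTRUE(res$wide_ci))
})

test_that("predict and the fitted closed form agree", {
  times <- seq(5, 95, by = 10)
  df <- data.frame(time_dt = times,
                   cells = gompertz_closed_form(times, params$C0,
                                                params$alpha1,
                                                params$alpha2))
  fit <- fit_gompertz(df, C0 = params$C0)
  expect_equal(predict(fit, times), df$cells, tolerance = 1e-5)
})
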