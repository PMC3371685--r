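params <- model_params()

test_that("holling activation has the saturating form", {
  expect_equal(holling_activation(0, 10), 0)
  expect_equal(holling_activation(10, 10), 0.5)
  expect_lt(abs(holling_activation(1e6, 10) - 1), 1e-4)
  expect_error(holling_activation(5, 0), "threshold")
  expect_error(holling_activation(-1, 10), "non-negative")
  # monotone non-decreasing over a grid
  grid <- sort(c(0, 10^(seq(-3, 8, by = 0.5))))
  expect_true(all(diff(holling_activation(grid, 10)) >= 0))
  expect_true(all(holling_activation(grid, 10) >= 0 &
                    holling_activation(grid, 10) < 1))
})

test_that("killing modulation interpolates between k2/k3 and 1", {
  expect_equal(killing_modulation(0, 1, 50), 0.02)
  expect_lt(abs(killing_modulation(1e9, 1, 50) - 1), 1e-6)
  expect_error(killing_modulation(0, 50, 50), "threshold")
  expect_error(killing_modulation(0, 60, 50), "threshold")
  grid <- sort(c(0, 10^(seq(-3, 9, by = 0.5))))
  v <- killing_modulation(grid, 1, 50)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0.02 & v < 1))
})

test_that("gompertz rate has the right roots and extinction floor", {
  expect_equal(gompertz_rate(1, params$alpha1, params$alpha2), 0.2165)
  expect_equal(gompertz_rate(0, params$alpha1, params$alpha2), 0)
  expect_equal(gompertz_rate(0.999, params$alpha1, params$alpha2), 0)
  plateau <- exp(params$alpha1 / params$alpha2)
  expect_equal(gompertz_rate(plateau, params$alpha1, params$alpha2), 0,
               tolerance = 1e-8)
  expect_lt(gompertz_rate(plateau * 2, params$alpha1, params$alpha2), 0)
  expect_gt(gompertz_rate(plateau / 2, params$alpha1, params$alpha2), 0)
})

test_that("pre-treatment state only moves through the tumour equation", {
  s0 <- initial_state(params)
  d <- melanoma_rhs(s0, s0, params)
  expect_equal(d[["N"]], 0) # N = M is the homeostatic equilibrium
  expect_equal(d[["C"]],
               gompertz_rate(params$C0, params$alpha1, params$alpha2))
  expect_equal(unname(d[c("E", "Ab", "Es", "As", "A")]), rep(0, 5))
})

test_that("without antibodies the kill term is reduced by k2/k3", {
  s <- c(E = 0, Ab = 0, Es = 1000, As = 0, N = params$M, C = 1e5, A = 0)
  d <- melanoma_rhs(s, s, params)
  kill <- gompertz_rate(1e5, params$alpha1, params$alpha2) - d[["C"]]
  expect_equal(kill, params$alpha3 * (params$k2 / params$k3) * 1000 * 1e5)
  # 50-fold weaker than the saturated rate with the default thresholds
  s_sat <- s; s_sat[["As"]] <- 1e12
  d_sat <- melanoma_rhs(s_sat, s_sat, params)
  kill_sat <- gompertz_rate(1e5, params$alpha1, params$alpha2) - d_sat[["C"]]
  expect_equal(kill_sat / kill, 50, tolerance = 1e-6)
})

test_that("rhs agrees with the term-by-term oracle on random states", {
  set.seed(42)
  for (i in 1:25) {
    s <- c(E = runif(1, 0, 1e6), Ab = runif(1, 0, 1e6),
           Es = runif(1, 0, 1e6), As = runif(1, 0, 1e5),
           N = runif(1, 0, 3e5), C = runif(1, 0, 1e7),
           A = runif(1, 0, 1e3))
    sd_ <- c(E = runif(1, 0, 1e6), Ab = runif(1, 0, 1e6),
             Es = 0, As = 0, N = params$M, C = params$C0, A = 0)
    inj <- runif(2, 0, 1e4)
    expect_equal(melanoma_rhs(s, sd_, params, inj),
                 oracle_rhs(s, sd_, params, inj), tolerance = 1e-12)
  }
})

test_that("rhs is exactly linear in the injection rates", {
  s <- initial_state(params)
  d0 <- melanoma_rhs(s, s, params, c(0, 0))
  d1 <- melanoma_rhs(s, s, params, c(100, 300))
  d2 <- melanoma_rhs(s, s, params, c(200, 600))
  expect_equal(d1 - d0, (d2 - d0) / 2)
  expect_equal(d1[["E"]] - d0[["E"]], 100)
  expect_equal(d1[["Ab"]] - d0[["Ab"]], 300)
})

test_that("derivatives are finite and dN <= 0 at the homeostatic ceiling", {
  set.seed(7)
  for (i in 1:20) {
    s <- c(E = runif(1, 0, 1e8), Ab = runif(1, 0, 1e8),
           Es = runif(1, 0, 1e8), As = runif(1, 0, 1e8),
           N = params$M, C = runif(1, 0, 1e8), A = runif(1, 0, 1e6))
    d <- melanoma_rhs(s, s, params)
    expect_true(all(is.finite(d)))
    expect_lte(d[["N"]], 0)
  }
})

test_that("negative states are rejected by the checked RHS", {
  s <- initial_state(params)
  bad <- s; bad[["C"]] <- -1
  expect_error(melanoma_rhs(bad, s, params), "negative state")
  expect_error(melanoma_rhs(s, bad, params), "negative state")
})
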