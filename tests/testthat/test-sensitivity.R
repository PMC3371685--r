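params <- model_params()

test_that("latin hypercube samples put one point in each stratum", {
  rng <- tibble::tibble(parameter = "x", lower = 2, upper = 12)
  X <- lhs_sample(rng, 10, seed = 5)
  strata <- findInterval(sort(X$x), seq(2, 12, length.out = 11),
                         rightmost.closed = TRUE)
  expect_identical(strata, 1:10)
  # multi-dimensional: every column stratified
  rng2 <- default_ranges(params)
  X2 <- lhs_sample(rng2, 20, seed = 5)
  for (j in names(X2)) {
    lo <- rng2$lower[rng2$parameter == j]
    hi <- rng2$upper[rng2$parameter == j]
    strata <- findInterval(sort(X2[[j]]), seq(lo, hi, length.out = 21),
                           rightmost.closed = TRUE)
    expect_identical(strata, 1:20)
  }
})

test_that("lhs sampling is reproducible and validates input", {
  rng <- default_ranges(params)
  expect_identical(lhs_sample(rng, 50, seed = 9), lhs_sample(rng, 50, seed = 9))
  expect_error(lhs_sample(rng, 1), "sample-size")
  expect_error(lhs_sample(tibble::tibble(parameter = "x", lower = 1,
                                         upper = 1), 10), "lower < upper")
  # stratified-uniform expectation
  big <- lhs_sample(tibble::tibble(parameter = "u", lower = 0, upper = 1),
                    1000, seed = 1)
  expect_lt(abs(mean(big$u) - 0.5), 0.02)
})

test_that("default ranges cover the varied parameters and the dummy", {
  rng <- default_ranges(params)
  expect_setequal(rng$parameter,
                  c(paste0("alpha", 1:11), "h", "k1", "k2", "k3", "M",
                    "p", "q", "dummy"))
  expect_true(all(rng$lower < rng$upper))
  expect_equal(rng$lower[rng$parameter == "alpha3"], 0.5 * params$alpha3)
  expect_equal(rng$upper[rng$parameter == "p"], 2 * params$p)
  expect_equal(unlist(rng[rng$parameter == "dummy", c("lower", "upper")]),
               c(lower = 0, upper = 1))
  # fit-driven ranges replace the growth-parameter defaults
  times <- seq(10, 100, 10)
  fit <- fit_gompertz(data.frame(
    time_dt = times,
    cells = gompertz_closed_form(times, params$C0, params$alpha1,
                                 params$alpha2) * exp(0.03 * sin(times))
  ), C0 = params$C0)
  rng2 <- default_ranges(params, gompertz_fit = fit)
  expect_equal(rng2$lower[rng2$parameter == "alpha1"],
               fit$coefficients$conf.low[fit$coefficients$term == "alpha1"])
  expect_lt(rng2$upper[rng2$parameter == "alpha2"] -
              rng2$lower[rng2$parameter == "alpha2"],
            params$alpha2) # fit CIs are much tighter than +/-50%
})

test_that("prcc identifies perfect monotone dependence", {
  rng <- tibble::tibble(parameter = paste0("x", 1:4),
                        lower = rep(0, 4), upper = rep(1, 4))
  X <- lhs_sample(rng, 100, seed = 3)
  res <- prcc(X, X$x2)
  expect_lt(abs(res$prcc[res$parameter == "x2"] - 1), 1e-6)
  expect_lt(res$p_value[res$parameter == "x2"], 1e-10)
  expect_true(all(abs(res$prcc[res$parameter != "x2"]) < 0.15))
})

test_that("prcc is invariant under strictly monotone transforms", {
  rng <- tibble::tibble(parameter = paste0("x", 1:3),
                        lower = rep(0, 3), upper = rep(1, 3))
  X <- lhs_sample(rng, 200, seed = 8)
  y <- X$x1 - 0.5 * X$x2 + withr::with_seed(8, rnorm(200, sd = 0.1))
  a <- prcc(X, y)
  b <- prcc(X, exp(y))               # monotone transform of the output
  expect_equal(a$prcc, b$prcc, tolerance = 1e-12)
  X2 <- X
  X2$x1 <- qlogis(X2$x1 / 1.0000001 + 1e-9) # monotone transform of an input
  expect_equal(prcc(X2, y)$prcc, a$prcc, tolerance = 1e-10)
})

test_that("prcc reduces to Spearman correlation when k = 1", {
  set.seed(12)
  x <- matrix(runif(80), ncol = 1, dimnames = list(NULL, "x"))
  y <- x[, 1]^2 + rnorm(80, sd = 0.2)
  expect_equal(prcc(x, y)$prcc,
               cor(x[, 1], y, method = "spearman"), tolerance = 1e-12)
})

test_that("prcc matches the inverse-correlation-matrix route", {
  rng <- tibble::tibble(parameter = paste0("x", 1:5),
                        lower = rep(0, 5), upper = rep(1, 5))
  X <- lhs_sample(rng, 150, seed = 21)
  y <- 2 * X$x1 - X$x3 + X$x4^3 + withr::with_seed(22, rnorm(150, sd = 0.3))
  expect_equal(prcc(X, y)$prcc, oracle_prcc_inverse(X, y),
               tolerance = 1e-10)
})

test_that("a dummy input stays at noise level", {
  rng <- tibble::tibble(parameter = c(paste0("x", 1:4), "dummy"),
                        lower = rep(0, 5), upper = rep(1, 5))
  ok <- vapply(1:20, function(s) {
    X <- lhs_sample(rng, 500, seed = 1000 + s)
    y <- X$x1 + 0.5 * X$x2 - X$x3 +
      withr::with_seed(2000 + s, rnorm(500, sd = 0.2))
    res <- prcc(X, y)
    d <- res[res$parameter == "dummy", ]
    abs(d$prcc) < 0.1 && d$p_value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate prcc inputs are rejected", {
  X <- matrix(runif(60), ncol = 3, dimnames = list(NULL, paste0("x", 1:3)))
  expect_error(prcc(X, rep(1, 20)), "constant output")
  Xc <- X; Xc[, 2] <- 5
  expect_error(prcc(Xc, runif(20)), "constant sample column")
  expect_error(prcc(X[1:4, ], runif(4)), "insufficient samples")
  expect_error(prcc(X, runif(7)), "one value per sample row")
})

test_that("prcc timecourse recovers the killing-rate sensitivity", {
  # vary only the killing rate (plus the dummy): after the treatment takes
  # effect its correlation with the tumour burden must be strongly negative
  rng <- tibble::tibble(
    parameter = c("alpha3", "dummy"),
    lower = c(0.5 * params$alpha3, 0),
    upper = c(1.5 * params$alpha3, 1)
  )
  pt <- prcc_timecourse(params, ranges = rng, n = 40,
                        output_times = c(6, 30, 45, 60), seed = 42)
  tb <- tibble::as_tibble(pt)
  post <- tb[tb$time_dt >= 30 & tb$parameter == "alpha3", ]
  expect_true(all(post$prcc < -0.9))
  expect_true(all(post$significant))
  # pre-treatment the burden is identical across rows (neither varied
  # parameter can act yet): a constant output has no defined PRCC
  pre <- tb[tb$time_dt == 6, ]
  expect_true(all(is.na(pre$prcc)))
  expect_true(all(!pre$significant))
  expect_true(all(tb$prcc >= -1 & tb$prcc <= 1, na.rm = TRUE))
  expect_identical(attr(pt, "n_failed"), 0)
})

test_that("prcc timecourse validates inputs", {
  expect_error(prcc_timecourse(params, n = 10, output_times = 200),
               "output_times")
  rng <- tibble::tibble(parameter = "nonexistent", lower = 0, upper = 1)
  expect_error(prcc_timecourse(params, ranges = rng, n = 10, seed = 1),
               "unknown model parameter")
  expect_error(prcc_timecourse(params, n = 10, output = "X"), "output")
})
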