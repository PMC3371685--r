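# Independent oracles used across the suite. These are deliberately written
# term by term from the model equations, without reusing any package
# internals beyond the parameter list, so they can catch sign/term errors
# in the production RHS and integrator.

# Hand-expanded scalar right-hand side, one line per equation.
oracle_rhs <- function(s, sd_, prm, inj = c(0, 0)) {
  E <- s[["E"]]; Ab <- s[["Ab"]]; Es <- s[["Es"]]; As <- s[["As"]]
  N <- s[["N"]]; C <- s[["C"]]; A <- s[["A"]]
  dE <- inj[1] - prm$alpha11 * E - prm$alpha8 * E
  dAb <- inj[2] - prm$alpha11 * Ab - prm$alpha10 * Ab
  dEs <- prm$alpha7 * (As / (As + prm$k1)) * Es +
    prm$alpha11 * sd_[["E"]] + prm$alpha6 * N * A - prm$alpha8 * Es
  dAs <- prm$alpha11 * sd_[["Ab"]] - prm$alpha9 * As * Es - prm$alpha10 * As
  dN <- prm$h * (prm$M - N) - prm$alpha6 * N * A
  growth <- if (C < 1) 0 else (prm$alpha1 - prm$alpha2 * log(C)) * C
  kill <- prm$alpha3 * ((As + prm$k2) / (As + prm$k3)) * Es * C
  dC <- growth - kill
  dA <- prm$alpha4 * kill - prm$alpha5 * A - prm$alpha6 * N * A
  c(E = dE, Ab = dAb, Es = dEs, As = dAs, N = dN, C = dC, A = dA)
}

# Explicit first-order (Euler) method-of-steps integrator on a fine fixed
# grid, with impulses applied at their node before departure and clamping
# at zero. Delay handled by direct index lookup into the full history.
oracle_euler_dde <- function(prm, schedule, horizon, h) {
  n <- round(horizon / h)
  tau_steps <- round(prm$tau / h)
  ev_steps <- if (nrow(schedule) > 0) round(schedule$time_dt / h) else integer()
  vars <- c("E", "Ab", "Es", "As", "N", "C", "A")
  Y <- matrix(0, n + 1, 7, dimnames = list(NULL, vars))
  y0 <- c(0, 0, 0, 0, prm$M, prm$C0, 0)
  Y[1, ] <- y0
  for (j in 0:(n - 1)) {
    for (e in which(ev_steps == j)) {
      Y[j + 1, "E"] <- Y[j + 1, "E"] + schedule$dE[e]
      Y[j + 1, "Ab"] <- Y[j + 1, "Ab"] + schedule$dAb[e]
    }
    yd <- if (j - tau_steps < 0) y0 else Y[j - tau_steps + 1, ]
    names(yd) <- vars
    y <- Y[j + 1, ]
    ynew <- y + h * oracle_rhs(y, yd, prm)
    Y[j + 2, ] <- pmax(ynew, 0)
  }
  for (e in which(ev_steps == n)) {
    Y[n + 1, "E"] <- Y[n + 1, "E"] + schedule$dE[e]
    Y[n + 1, "Ab"] <- Y[n + 1, "Ab"] + schedule$dAb[e]
  }
  list(times = seq(0, by = h, length.out = n + 1), states = Y)
}

# Fine-step RK4 integration of the scalar Gompertz ODE, independent of the
# closed-form expression.
oracle_gompertz_ode <- function(C0, alpha1, alpha2, t_end, h = 1e-3) {
  f <- function(C) (alpha1 - alpha2 * log(C)) * C
  n <- round(t_end / h)
  C <- C0
  for (i in seq_len(n)) {
    k1 <- f(C)
    k2 <- f(C + h / 2 * k1)
    k3 <- f(C + h / 2 * k2)
    k4 <- f(C + h * k3)
    C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  C
}

# Brute-force partial correlation of ranked data through the inverse of the
# correlation matrix (a second, algebraically different route to the PRCC).
oracle_prcc_inverse <- function(X, y) {
  R <- apply(cbind(as.matrix(X), y), 2, rank)
  P <- solve(stats::cor(R))
  k <- ncol(X)
  vapply(seq_len(k), function(j) {
    -P[j, k + 1] / sqrt(P[j, j] * P[k + 1, k + 1])
  }, numeric(1))
}

# relative discrepancy with an absolute floor (for components that pass
# through zero)
rel_err <- function(a, b, floor = 1) {
  abs(a - b) / pmax(pmax(abs(a), abs(b)), floor)
}
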