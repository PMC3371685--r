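# State vector layout shared by the RHS and the integrator. Order matters:
# E, Ab live in the injection-point compartment; Es, As, N, C, A in the skin.
state_vars <- function() c("E", "Ab", "Es", "As", "N", "C", "A")

#' Holling type II activation factor
#'
#' Saturating response `As / (As + k1)` through which skin-compartment
#' antibodies boost the duplication of activated CTLs. The factor is 0
#' without antibodies, 1/2 at the half-saturation threshold `k1`, and tends
#' to 1 as the antibody count grows, at which point CTLs duplicate at their
#' maximum rate `alpha7`.
#'
#' @param As Antibody count in the skin compartment (non-negative; may be a
#'   vector).
#' @param k1 Half-saturation threshold (antibody count, strictly positive).
#' @return The activation fraction in `[0, 1)`, strictly increasing in `As`.
#' @examples
#' holling_activation(0, 10)   # no antibodies, no boost
#' holling_activation(10, 10)  # half saturation
#' @export
holling_activation <- function(As, k1) {
  if (!is.numeric(k1) || length(k1) != 1 || !is.finite(k1) || k1 <= 0) {
    stop("invalid threshold: k1 must be a single positive number",
         call. = FALSE)
  }
  if (any(As < 0)) stop("As must be non-negative", call. = FALSE)
  As / (As + k1)
}

#' Antibody-modulated killing factor
#'
#' The factor `(As + k2) / (As + k3)` scaling the melanoma killing rate of
#' skin-resident activated CTLs. With no antibodies it equals `k2 / k3`
#' (lower killing because CTLs infiltrate the tumour mass poorly); with many
#' antibodies it tends to 1 (maximum killing). Requires `k2 < k3`.
#'
#' @param As Antibody count in the skin compartment (non-negative; may be a
#'   vector).
#' @param k2 Minimum-killing threshold (antibody count).
#' @param k3 Maximum-killing threshold (antibody count), `k3 > k2 > 0`.
#' @return The killing fraction in `[k2/k3, 1)`, strictly increasing in `As`.
#' @examples
#' killing_modulation(0, 1, 50)    # = 1/50, antibody-free killing
#' killing_modulation(1e9, 1, 50)  # ~ 1, maximum killing
#' @export
killing_modulation <- function(As, k2, k3) {
  if (!is.numeric(k2) || !is.numeric(k3) || length(k2) != 1 ||
      length(k3) != 1 || !is.finite(k2) || !is.finite(k3) ||
      k2 <= 0 || k2 >= k3) {
    stop("invalid thresholds: require 0 < k2 < k3 (k2 << k3)", call. = FALSE)
  }
  if (any(As < 0)) stop("As must be non-negative", call. = FALSE)
  (As + k2) / (As + k3)
}

#' Gompertz net growth rate of the melanoma population
#'
#' Evaluates `(alpha1 - alpha2 * log(C)) * C`, the Gompertzian growth term
#' of the melanoma equation. The rate is positive below the carrying level
#' `exp(alpha1/alpha2)`, zero at it, and negative above it. For `C < 1` the
#' rate is defined as 0: fewer than one cell cannot proliferate and the
#' logarithm diverges at 0, so therapy-driven extinction parks the
#' population rather than resurrecting it.
#'
#' @param C Melanoma cell count (non-negative; may be a vector).
#' @param alpha1 Growth rate, per \eqn{\Delta t}.
#' @param alpha2 Shrink rate, per \eqn{\Delta t}, strictly positive.
#' @return Net growth rate in cells per \eqn{\Delta t}.
#' @examples
#' gompertz_rate(1, 0.2165, 0.01269)   # = alpha1
#' gompertz_rate(exp(0.2165 / 0.01269), 0.2165, 0.01269) # plateau: 0
#' @export
gompertz_rate <- function(C, alpha1, alpha2) {
  if (any(C < 0)) stop("C must be non-negative", call. = FALSE)
  out <- numeric(length(C))
  live <- C >= 1
  out[live] <- (alpha1 - alpha2 * log(C[live])) * C[live]
  out
}

#' Right-hand side of the melanoma--immune DDE system
#'
#' Evaluates the seven coupled derivatives of the two-compartment model at
#' one time point. The injection-point populations `E` (activated OT1 CTLs)
#' and `Ab` (anti-CD137 antibodies) decay by migration and death/
#' degradation; migration feeds the skin populations `Es` and `As` after a
#' delay `tau`, which is why the delayed state enters. In the skin,
#' antibodies boost CTL duplication (Holling type II in `As`) and CTL
#' killing of melanoma cells (the `(As+k2)/(As+k3)` factor); killed
#' melanoma cells release antigens `A` that convert naive CTLs `N` into
#' activated ones, while the naive pool relaxes back towards its
#' homeostatic level `M`.
#'
#' Treatment boluses are handled as instantaneous state jumps by the
#' integrator, not here; the continuous inflow arguments exist so the RHS
#' stays a pure function and default to zero.
#'
#' @param state Named numeric vector with components
#'   `E, Ab, Es, As, N, C, A` (all non-negative), the state at time `t`.
#' @param delayed_state The state at time `t - tau`, same layout.
#' @param params A [model_params()] object.
#' @param injection_rates Length-2 numeric: continuous inflow rates into
#'   `E` and `Ab` (cells resp. antibodies per \eqn{\Delta t}). Default zero.
#' @return Named numeric vector of the seven derivatives, per
#'   \eqn{\Delta t}.
#' @examples
#' params <- model_params()
#' s0 <- c(E = 0, Ab = 0, Es = 0, As = 0,
#'         N = params$M, C = params$C0, A = 0)
#' melanoma_rhs(s0, s0, params) # only dC is nonzero before treatment
#' @export
melanoma_rhs <- function(state, delayed_state, params,
                         injection_rates = c(0, 0)) {
  validate_params(params)
  state <- as_state(state)
  delayed_state <- as_state(delayed_state)
  if (any(state < 0) || any(delayed_state < 0)) {
    stop("negative state component passed to the RHS ",
         "(integrator clamping failure?)", call. = FALSE)
  }
  if (length(injection_rates) != 2 || any(!is.finite(injection_rates))) {
    stop("injection_rates must be two finite numbers", call. = FALSE)
  }
  d <- rhs_raw(state, delayed_state, params, injection_rates)
  names(d) <- state_vars()
  d
}

# Unchecked scalar RHS used by both the exported wrapper and the
# integrator's inner loop. y and yd are length-7 vectors in state_vars()
# order; inj is c(inflow_E, inflow_Ab).
rhs_raw <- function(y, yd, prm, inj = c(0, 0)) {
  E <- y[1]; Ab <- y[2]; Es <- y[3]; As <- y[4]
  N <- y[5]; C <- y[6]; A <- y[7]
  holl <- As / (As + prm$k1)
  km <- (As + prm$k2) / (As + prm$k3)
  growth <- if (C >= 1) (prm$alpha1 - prm$alpha2 * log(C)) * C else 0
  kill <- prm$alpha3 * km * Es * C
  c(
    inj[1] - (prm$alpha11 + prm$alpha8) * E,
    inj[2] - (prm$alpha11 + prm$alpha10) * Ab,
    prm$alpha7 * holl * Es + prm$alpha11 * yd[1] + prm$alpha6 * N * A -
      prm$alpha8 * Es,
    prm$alpha11 * yd[2] - prm$alpha9 * As * Es - prm$alpha10 * As,
    prm$h * (prm$M - N) - prm$alpha6 * N * A,
    growth - kill,
    prm$alpha4 * kill - prm$alpha5 * A - prm$alpha6 * N * A
  )
}

as_state <- function(x) {
  vars <- state_vars()
  if (is.data.frame(x)) x <- unlist(x[1, intersect(vars, names(x))])
  if (!is.numeric(x) || length(x) != 7) {
    stop("a state must be a numeric vector of length 7 (E, Ab, Es, As, N, C, A)",
         call. = FALSE)
  }
  if (!is.null(names(x)) && all(vars %in% names(x))) x <- x[vars]
  x <- as.numeric(x)
  names(x) <- vars
  x
}

#' Pre-treatment initial state
#'
#' The Cauchy initial conditions of the model: no treatment-derived
#' populations anywhere (`E = Ab = Es = As = A = 0`), the naive CTL pool at
#' its homeostatic level (`N = M`) and the inoculated melanoma burden
#' (`C = C0`).
#'
#' @param params A [model_params()] object.
#' @return Named numeric state vector.
#' @export
initial_state <- function(params) {
  validate_params(params)
  s <- c(E = 0, Ab = 0, Es = 0, As = 0,
         N = params$M, C = params$C0, A = 0)
  s
}
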