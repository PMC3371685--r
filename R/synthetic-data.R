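#' Generate a synthetic cohort of melanoma surface measurements
#'
#' Emulates the in vivo measurement stream the growth-curve fitting stage
#' consumes: per-mouse melanoma surface (mm^2) time series over a ~30-day
#' experiment. Each mouse's tumour follows Gompertz kinetics from the
#' inoculated burden `C0`; its cell count at each observation day is
#' converted to a surface under the disk-monolayer assumption and then
#' perturbed by multiplicative lognormal noise `exp(sigma * Z)`,
#' `Z ~ N(0, 1)` (areas are positive and measurement error scales with
#' size). Optional inter-mouse variability draws each mouse's
#' `(alpha1, alpha2)` from a normal distribution around the cohort truth
#' with coefficient of variation `mouse_cv`, emulating biological spread;
#' the per-mouse truth is recorded in the output, so at `noise_sigma = 0`
#' the generated surfaces equal the noiseless conversion of each mouse's
#' own growth curve exactly.
#'
#' What this generator does *not* emulate: the detection delay of small
#' early tumours (a real melanoma takes days to become measurable on the
#' skin), measurement censoring, or treated-arm kinetics.
#'
#' @param params A [model_params()] object supplying the cohort-level truth
#'   (`alpha1`, `alpha2`, `C0`).
#' @param n_mice Number of mice (default 5, the in vivo group size).
#' @param days Observation days; default every third day from 6 to 30.
#' @param noise_sigma Lognormal measurement noise sd on the log scale
#'   (default 0.05, i.e. ~5% error); must be non-negative.
#' @param mouse_cv Coefficient of variation of the per-mouse growth
#'   parameters (default 0.05; 0 disables inter-mouse spread).
#' @inheritParams cells_to_surface
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   bit for bit.
#' @return A tibble with one row per mouse and day: `mouse_id`, `day`,
#'   `time_dt`, `cells_true`, `surface_true_mm2`, `surface_mm2`,
#'   `alpha1_true`, `alpha2_true`; generator settings ride along as
#'   attributes.
#' @examples
#' cohort <- generate_cohort(model_params(), seed = 42)
#' head(cohort, 3)
#' @export
generate_cohort <- function(params, n_mice = 5, days = seq(6, 30, by = 3),
                            noise_sigma = 0.05, mouse_cv = 0.05,
                            cell_diameter = 0.02, packing = 1, seed = NULL) {
  validate_params(params)
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1 ||
      noise_sigma < 0) {
    stop("noise_sigma must be a single non-negative number", call. = FALSE)
  }
  if (n_mice < 1) stop("n_mice must be at least 1", call. = FALSE)
  if (mouse_cv < 0) stop("mouse_cv must be non-negative", call. = FALSE)
  gen <- function() {
    purrr::map(seq_len(n_mice), function(m) {
      a1 <- params$alpha1
      a2 <- params$alpha2
      if (mouse_cv > 0) {
        # truncate at half nominal so a jittered mouse stays a growing tumour
        a1 <- max(stats::rnorm(1, a1, mouse_cv * a1), a1 / 2)
        a2 <- max(stats::rnorm(1, a2, mouse_cv * a2), a2 / 2)
      }
      t_dt <- days_to_dt(days, params$dt_hours)
      cells <- gompertz_closed_form(t_dt, params$C0, a1, a2)
      s_true <- cells_to_surface(cells, cell_diameter, packing)
      noise <- if (noise_sigma > 0) {
        exp(noise_sigma * stats::rnorm(length(days)))
      } else rep(1, length(days))
      tibble::tibble(
        mouse_id = sprintf("m%02d", m),
        day = days,
        time_dt = t_dt,
        cells_true = cells,
        surface_true_mm2 = s_true,
        surface_mm2 = s_true * noise,
        alpha1_true = a1,
        alpha2_true = a2
      )
    }) |> dplyr::bind_rows()
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(out,
            noise_sigma = noise_sigma, mouse_cv = mouse_cv,
            cell_diameter = cell_diameter, packing = packing,
            seed = seed, C0 = params$C0,
            class = c("melimm_cohort", class(out)))
}

#' Pool a measured cohort into per-day counts for fitting
#'
#' Converts each surface measurement back to a cell count (same diameter
#' and packing the measurement conversion assumes) and returns the long
#' table [fit_gompertz()] consumes; optionally aggregated to the per-day
#' mean count, the analogue of fitting the cohort's mean growth curve.
#'
#' @param cohort A data frame with columns `day` and `surface_mm2`
#'   (e.g. from [generate_cohort()] or read from a measurements CSV).
#' @inheritParams cells_to_surface
#' @param aggregate Average counts per day before returning? Default
#'   `TRUE`.
#' @return A tibble with columns `time_dt`, `day`, `cells`.
#' @export
cohort_counts <- function(cohort, cell_diameter = 0.02, packing = 1,
                          aggregate = TRUE) {
  if (!all(c("day", "surface_mm2") %in% names(cohort))) {
    stop("cohort needs columns day and surface_mm2", call. = FALSE)
  }
  tbl <- tibble::as_tibble(cohort) |>
    dplyr::mutate(cells = surface_to_cells(.data$surface_mm2,
                                           cell_diameter, packing))
  if (aggregate) {
    tbl <- tbl |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(cells = mean(.data$cells), .groups = "drop")
  }
  tbl |>
    dplyr::mutate(time_dt = days_to_dt(.data$day)) |>
    dplyr::select("time_dt", "day", "cells")
}
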