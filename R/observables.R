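#' Convert melanoma cell counts to tumour surface and back
#'
#' The melanoma is assumed to grow only radially (its first growth phase),
#' as a disk-shaped monolayer on the skin: the visible surface is the sum
#' of the cross-sections of its cells, so surface and cell count are
#' proportional. `cells_to_surface()` returns
#' `C * pi * (cell_diameter/2)^2 / packing` and `surface_to_cells()` is its
#' exact inverse (real-valued: the fitting stage consumes it, so no
#' rounding). The mean melanoma cell diameter is an assumption of this
#' package, defaulting to 0.02 mm (a typical B16 cell scale); `packing`
#' optionally dilutes the monolayer (cells covering a fraction `packing` of
#' the disk).
#'
#' @param C Melanoma cell count (non-negative; vectorised).
#' @param S Melanoma surface in mm^2 (non-negative; vectorised).
#' @param cell_diameter Mean melanoma cell diameter, mm.
#' @param packing Fraction of the disk covered by cells, in (0, 1].
#' @return Surface in mm^2, resp. a real-valued cell count.
#' @examples
#' cells_to_surface(180000)          # the inoculated burden, in mm^2
#' surface_to_cells(56.55)           # ~ 1.8e5 cells at the default diameter
#' @export
cells_to_surface <- function(C, cell_diameter = 0.02, packing = 1) {
  check_conversion_args(cell_diameter, packing)
  if (any(C < 0)) stop("C must be non-negative", call. = FALSE)
  C * pi * (cell_diameter / 2)^2 / packing
}

#' @rdname cells_to_surface
#' @export
surface_to_cells <- function(S, cell_diameter = 0.02, packing = 1) {
  check_conversion_args(cell_diameter, packing)
  if (any(S < 0)) stop("S must be non-negative", call. = FALSE)
  S * packing / (pi * (cell_diameter / 2)^2)
}

check_conversion_args <- function(cell_diameter, packing) {
  if (!is.numeric(cell_diameter) || length(cell_diameter) != 1 ||
      !is.finite(cell_diameter) || cell_diameter <= 0) {
    stop("cell_diameter must be a single positive number (mm)", call. = FALSE)
  }
  if (!is.numeric(packing) || length(packing) != 1 || packing <= 0 ||
      packing > 1) {
    stop("packing must be in (0, 1]", call. = FALSE)
  }
}

#' Symmetric relative difference between two measurements
#'
#' The comparison metric `d(x, y) = |x - y| / ((|x| + |y|) / 2)`, used to
#' contrast simulated and measured melanoma surfaces. It is symmetric and
#' bounded in `[0, 2]`; the degenerate point `x = y = 0` is defined as 0
#' (the limit along identical values).
#'
#' @param x,y Numeric vectors (recycled to a common length).
#' @return The relative difference(s), in `[0, 2]`.
#' @examples
#' relative_difference(5, 5)  # 0
#' relative_difference(7, 0)  # 2, the maximum
#' relative_difference(1, 3)  # 1
#' @export
relative_difference <- function(x, y) {
  denom <- (abs(x) + abs(y)) / 2
  out <- abs(x - y) / denom
  out[denom == 0] <- 0
  out
}

#' Simulated melanoma surface at observation days
#'
#' Reads the melanoma cell count of a trajectory at the requested days and
#' converts it to a surface, producing the in-silico series that is
#' compared against in vivo surface measurements.
#'
#' @param trajectory A `melimm_trajectory`.
#' @param sample_days Observation days (within the simulated horizon).
#' @inheritParams cells_to_surface
#' @return A tibble with columns `day`, `time_dt`, `cells`, `surface_mm2`
#'   and `source = "simulated"`.
#' @export
surface_timeseries <- function(trajectory, sample_days,
                               cell_diameter = 0.02, packing = 1) {
  st <- state_at_day(trajectory, sample_days)
  tibble::tibble(
    day = st$day,
    time_dt = st$time_dt,
    cells = st$C,
    surface_mm2 = cells_to_surface(st$C, cell_diameter, packing),
    source = "simulated"
  )
}

#' Compare simulated and measured surface series
#'
#' Joins an in-silico surface series with a measured one on shared days and
#' computes absolute and symmetric relative differences.
#'
#' @param simulated A data frame with columns `day` and `surface_mm2`
#'   (e.g. from [surface_timeseries()]).
#' @param measured A data frame with columns `day` and `surface_mm2`
#'   (e.g. a per-day mean of a measured or synthetic cohort).
#' @return A tibble with columns `day`, `surface_insilico_mm2`,
#'   `surface_invivo_mm2`, `abs_diff`, `rel_diff`.
#' @export
compare_surfaces <- function(simulated, measured) {
  for (nm in list(simulated, measured)) {
    if (!all(c("day", "surface_mm2") %in% names(nm))) {
      stop("both series need columns day and surface_mm2", call. = FALSE)
    }
  }
  sim <- dplyr::select(tibble::as_tibble(simulated), "day",
                       surface_insilico_mm2 = "surface_mm2")
  mea <- dplyr::select(tibble::as_tibble(measured), "day",
                       surface_invivo_mm2 = "surface_mm2")
  dplyr::inner_join(sim, mea, by = "day") |>
    dplyr::mutate(
      abs_diff = abs(.data$surface_insilico_mm2 - .data$surface_invivo_mm2),
      rel_diff = relative_difference(.data$surface_insilico_mm2,
                                     .data$surface_invivo_mm2)
    )
}
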