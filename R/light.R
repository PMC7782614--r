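#' Light attenuation coefficient from Secchi depth
#'
#' Converts Secchi depth to a diffuse light attenuation coefficient with
#' the classical reciprocal relation `k = C / sd`. The default constant
#' `C = 1.7` is the Poole-Atkins value; it is exposed as an argument
#' because the appropriate constant varies somewhat between water bodies.
#'
#' @param sd Secchi depth, m (> 0). Vectorised.
#' @param constant Conversion constant `C` (dimensionless, default 1.7).
#' @return Attenuation coefficient k, m^-1.
#' @examples
#' attenuation_from_secchi(1.7) # 1
#' attenuation_from_secchi(8.5) # 0.2
#' @export
attenuation_from_secchi <- function(sd, constant = 1.7) {
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    abort("Secchi depth must be finite and > 0.")
  }
  constant / sd
}

#' Surface photon flux density from solar irradiance
#'
#' Converts broadband solar irradiance (W m^-2) to photosynthetic photon
#' flux density using the standard marine-optics factor of 4.15
#' micromol photons per joule of broadband solar energy.
#'
#' @param irradiance Solar irradiance, W m^-2 (>= 0). Vectorised.
#' @param factor Conversion factor (default 4.15).
#' @return PFD, micromol photons m^-2 s^-1.
#' @examples
#' pfd_surface(1)   # 4.15
#' pfd_surface(100) # 415
#' @export
pfd_surface <- function(irradiance, factor = 4.15) {
  if (any(!is.finite(irradiance)) || any(irradiance < 0)) {
    abort("Irradiance must be finite and >= 0.")
  }
  factor * irradiance
}

#' Photon flux density at eelgrass canopy height
#'
#' Beer's law `I_z = I_0 * exp(-k * z)` evaluated 0.5 m above the sea
#' floor, roughly the top of the eelgrass canopy: the evaluation depth is
#' `z = max(d - canopy_offset, 0)`. No surface-reflection or
#' surface-roughness correction is applied by default (plane-surface
#' simplification; roughly 6% of incident light is actually reflected, so
#' a slight overestimate ensues). Set `reflection` to a fraction to
#' subtract it.
#'
#' @param i0 Surface PFD, micromol photons m^-2 s^-1 (>= 0).
#' @param k Attenuation coefficient, m^-1 (>= 0).
#' @param d Water depth, m (> 0; land cells are invalid input).
#' @param canopy_offset Height above the sea floor at which light is
#'   evaluated, m (default 0.5).
#' @param reflection Fraction of incident light reflected at the surface
#'   (default 0, i.e. plane-surface simplification).
#' @return PFD at canopy height, micromol photons m^-2 s^-1. Vectorised
#'   over all numeric arguments.
#' @examples
#' pfd_at_canopy(415, 0.5, 2.5) # 415 * exp(-1)
#' pfd_at_canopy(415, 2.0, 0.5) # clamps to surface value
#' @export
pfd_at_canopy <- function(i0, k, d, canopy_offset = 0.5, reflection = 0) {
  if (any(!is.finite(i0)) || any(i0 < 0)) abort("`i0` must be >= 0.")
  if (any(!is.finite(k)) || any(k < 0)) abort("`k` must be >= 0.")
  if (any(!is.finite(d)) || any(d <= 0)) {
    abort("`d` must be > 0 (land cells carry no canopy light).")
  }
  z <- pmax(d - canopy_offset, 0)
  (1 - reflection) * i0 * exp(-k * z)
}

#' Monthly surface-irradiance climatology
#'
#' Twelve monthly mean solar irradiances (W m^-2) for a single
#' representative position in the model region, applied over the entire
#' grid (the single-station simplification). The default is a synthetic
#' climatology shaped for ~54.5 degrees N: midsummer monthly means near
#' 235 W m^-2, midwinter near 20 W m^-2.
#'
#' @param values Optional replacement vector of 12 monthly irradiances.
#' @return A tibble with columns `month` (1-12) and `irradiance` (W m^-2).
#' @export
irradiance_climatology <- function(values = NULL) {
  if (is.null(values)) {
    values <- c(25, 55, 105, 165, 220, 235, 225, 190, 130, 70, 30, 18)
  }
  stopifnot(length(values) == 12, all(values >= 0))
  tibble::tibble(month = 1:12, irradiance = as.numeric(values))
}

#' Read an irradiance climatology from CSV
#'
#' Expects columns `month` (1-12) and `irradiance` (W m^-2).
#'
#' @param path CSV file path.
#' @return A 12-row tibble as from [irradiance_climatology()].
#' @export
read_irradiance <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("month", "irradiance") %in% names(df)))
  irradiance_climatology(df$irradiance[order(df$month)])
}

#' Slice-mean PFD predictor field
#'
#' Computes, for every in-scope cell, canopy-height PFD per month of the
#' irradiance climatology and per year of a time slice using that year's
#' attenuation coefficient, then averages over months and years. Because
#' a single irradiance climatology is applied everywhere, the monthly mean
#' commutes with Beer's law for a fixed year: the per-year field equals
#' `mean(PFD_surface(month)) * exp(-k z)`.
#'
#' @param secchi A per-year Secchi tibble from [make_secchi_series()] (or
#'   the same long format from real data).
#' @param grid A `depth_grid`.
#' @param years Years of the slice to average over (must be present in
#'   `secchi`).
#' @param irradiance Monthly climatology tibble
#'   (default [irradiance_climatology()]).
#' @param months Which months of the climatology enter the average
#'   (default all 12).
#' @param secchi_constant Secchi-to-k constant, passed to
#'   [attenuation_from_secchi()].
#' @inheritParams pfd_at_canopy
#' @return A tibble `row`, `col`, `pfd` over in-scope cells.
#' @export
pfd_predictor_field <- function(secchi, grid, years,
                                irradiance = irradiance_climatology(),
                                months = 1:12, secchi_constant = 1.7,
                                canopy_offset = 0.5, reflection = 0) {
  missing_years <- setdiff(years, unique(secchi$year))
  if (length(missing_years) > 0) {
    abort(paste0("Secchi series lacks years: ",
                 paste(missing_years, collapse = ", ")))
  }
  i0_mean <- mean(pfd_surface(irradiance$irradiance[irradiance$month %in% months]))

  depths <- dplyr::select(
    dplyr::filter(grid, .data$in_scope), "row", "col", "depth"
  )
  slice <- dplyr::inner_join(
    dplyr::filter(secchi, .data$year %in% .env$years),
    depths, by = c("row", "col")
  )
  slice$pfd <- pfd_at_canopy(
    i0_mean, attenuation_from_secchi(slice$secchi, secchi_constant),
    slice$depth, canopy_offset = canopy_offset, reflection = reflection
  )
  out <- dplyr::summarise(
    dplyr::group_by(slice, .data$row, .data$col),
    pfd = mean(.data$pfd), .groups = "drop"
  )
  dplyr::arrange(out, .data$row, .data$col)
}
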