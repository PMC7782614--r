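#' Constants of the maximum-wave chain
#'
#' Bundles the constants used to turn a significant wave height into the
#' maximum expected individual wave and its period: gravitational
#' acceleration, the Rayleigh sample size `n_waves` behind the
#' maximum-wave factor (`H_max = 1.86 * H_m0` for N = 1000 waves, since
#' `sqrt(ln(N)/2) = 1.8585...`), and the empirical period-height relation
#' `T_Hmax = 0.83 * H_max + 3.17`.
#'
#' @param g Gravitational acceleration, m s^-2.
#' @param n_waves Rayleigh sample size behind `hmax_factor`.
#' @param hmax_factor Maximum-wave factor (default 1.86).
#' @param period_slope,period_intercept Coefficients of the period
#'   relation, s m^-1 and s.
#' @return A named list of constants. Construction fails if `hmax_factor`
#'   is not within 0.005 of `sqrt(log(n_waves)/2)`.
#' @examples
#' wave_constants()$hmax_factor # 1.86
#' @export
wave_constants <- function(g = 9.81, n_waves = 1000, hmax_factor = 1.86,
                           period_slope = 0.83, period_intercept = 3.17) {
  if (abs(hmax_factor - sqrt(log(n_waves) / 2)) > 0.005) {
    abort("`hmax_factor` is inconsistent with sqrt(log(n_waves)/2).")
  }
  list(g = g, n_waves = n_waves, hmax_factor = hmax_factor,
       period_slope = period_slope, period_intercept = period_intercept)
}

#' Maximum wave height from significant wave height
#'
#' `H_max = 1.86 * H_m0`, the expected maximum of N = 1000
#' Rayleigh-distributed wave heights with `H_m0 ~ H_1/3`.
#'
#' @param hm0 Significant wave height, m (>= 0). Vectorised.
#' @param constants See [wave_constants()].
#' @return Maximum wave height, m.
#' @examples
#' hmax_from_hm0(1) # 1.86
#' @export
hmax_from_hm0 <- function(hm0, constants = wave_constants()) {
  if (any(!is.finite(hm0)) || any(hm0 < 0)) abort("`hm0` must be >= 0.")
  constants$hmax_factor * hm0
}

#' Period of the maximum wave
#'
#' Empirical relation `T_Hmax = 0.83 * H_max + 3.17` linking the maximum
#' wave height to its period.
#'
#' @param hmax Maximum wave height, m (>= 0). Vectorised.
#' @inheritParams hmax_from_hm0
#' @return Wave period, s.
#' @examples
#' thmax_from_hmax(0) # 3.17
#' @export
thmax_from_hmax <- function(hmax, constants = wave_constants()) {
  if (any(!is.finite(hmax)) || any(hmax < 0)) abort("`hmax` must be >= 0.")
  constants$period_slope * hmax + constants$period_intercept
}

#' Depth-limited breaking cap
#'
#' The maximum wave height cannot exceed the local water depth
#' (`H_max / d < 1`); implemented as the non-strict cap `min(hmax, d)`.
#'
#' @param hmax Maximum wave height, m. Vectorised.
#' @param d Water depth, m (> 0).
#' @return Capped maximum wave height, m.
#' @export
cap_breaking <- function(hmax, d) {
  if (any(!is.finite(d)) || any(d <= 0)) abort("`d` must be > 0.")
  pmin(hmax, d)
}

#' Wavelength from the linear dispersion relation
#'
#' Solves `L = (g T^2 / 2 pi) * tanh(2 pi d / L)` for the wavelength at
#' intermediate depth. A damped fixed-point iteration seeded at the
#' deep-water wavelength handles nearly all inputs; any element that has
#' not converged after `max_iter` iterations falls back to bisection on
#' `[1e-3, g T^2 / 2 pi]`.
#'
#' @param t Wave period, s (> 0). Vectorised with `d`.
#' @param d Water depth, m (> 0).
#' @param g Gravitational acceleration, m s^-2.
#' @param tol Absolute tolerance on the defining equation, m.
#' @param max_iter Iteration cap for the fixed-point stage.
#' @return Wavelength L, m, satisfying the dispersion relation to `tol`;
#'   always in `(0, g T^2 / 2 pi]`.
#' @examples
#' dispersion_wavelength(10, 1000) # deep water: ~156.1 m
#' dispersion_wavelength(5, 0.1)   # shallow water: ~ 5 * sqrt(9.81 * 0.1)
#' @export
dispersion_wavelength <- function(t, d, g = 9.81, tol = 1e-6,
                                  max_iter = 200) {
  if (any(!is.finite(t)) || any(t <= 0)) abort("`t` must be > 0.")
  if (any(!is.finite(d)) || any(d <= 0)) abort("`d` must be > 0.")
  n <- max(length(t), length(d))
  t <- rep_len(t, n)
  d <- rep_len(d, n)

  l0 <- g * t^2 / (2 * pi)
  l <- l0 * tanh(2 * pi * d / l0)^0.5 # good starting guess at all depths
  damp <- 0.5
  for (i in seq_len(max_iter)) {
    l_new <- l0 * tanh(2 * pi * d / l)
    l_next <- damp * l_new + (1 - damp) * l
    if (max(abs(l0 * tanh(2 * pi * d / l_next) - l_next)) < tol) {
      l <- l_next
      break
    }
    l <- l_next
  }
  residual <- abs(l0 * tanh(2 * pi * d / l) - l)
  bad <- which(residual >= tol)
  for (j in bad) {
    f <- function(x) l0[j] * tanh(2 * pi * d[j] / x) - x
    root <- stats::uniroot(f, c(1e-3, l0[j]), tol = tol / 10)
    l[j] <- root$root
    if (abs(f(l[j])) >= tol) {
      abort("Dispersion solver failed to converge.")
    }
  }
  l
}

#' Bottom orbital velocity under a wave
#'
#' Linear wave theory amplitude of the horizontal orbital velocity at the
#' sea floor: `U = pi * h / (t * sinh(2 pi d / L))` with `L` from
#' [dispersion_wavelength()].
#'
#' @param h Wave height, m (>= 0). Vectorised with `t`, `d`.
#' @param t Wave period, s (> 0).
#' @param d Water depth, m (> 0).
#' @param g Gravitational acceleration, m s^-2.
#' @return Orbital velocity, m s^-1 (0 where `h = 0`).
#' @examples
#' bottom_orbital_velocity(1, 5, 2) # ~0.99
#' @export
bottom_orbital_velocity <- function(h, t, d, g = 9.81) {
  if (any(!is.finite(h)) || any(h < 0)) abort("`h` must be >= 0.")
  l <- dispersion_wavelength(t, d, g = g)
  pi * h / (t * sinh(2 * pi * d / l))
}

#' Slice-mean maximum-orbital-velocity predictor field
#'
#' For every in-scope cell and slice year, chains significant wave height
#' through the maximum-wave statistics to the bed: `H_m0` is scaled to the
#' maximum expected wave `H_max`, capped at the local depth (breaking),
#' assigned its period `T_Hmax` *after* capping (the breaking criterion
#' constrains the physical wave that carries the period), and passed
#' through linear wave theory to the bottom orbital velocity. The slice
#' value is the arithmetic mean over years (set
#' `statistic = "percentile"` with `probs` for an upper-percentile
#' aggregate instead). Setting `period = "tm02"` uses the sea-state mean
#' period directly in the orbital formula for sensitivity runs.
#'
#' @param waves A per-year sea-state tibble from [make_wave_series()].
#' @param grid A `depth_grid`.
#' @param years Years of the slice to aggregate (must be present).
#' @param constants See [wave_constants()].
#' @param period `"thmax"` (default) or `"tm02"`.
#' @param statistic `"mean"` (default) or `"percentile"`.
#' @param probs Percentile used when `statistic = "percentile"`.
#' @return A tibble `row`, `col`, `mov` (m s^-1) over in-scope cells.
#' @export
mov_predictor_field <- function(waves, grid, years,
                                constants = wave_constants(),
                                period = c("thmax", "tm02"),
                                statistic = c("mean", "percentile"),
                                probs = 0.9) {
  period <- match.arg(period)
  statistic <- match.arg(statistic)
  missing_years <- setdiff(years, unique(waves$year))
  if (length(missing_years) > 0) {
    abort(paste0("Sea-state series lacks years: ",
                 paste(missing_years, collapse = ", ")))
  }
  depths <- dplyr::select(
    dplyr::filter(grid, .data$in_scope), "row", "col", "depth"
  )
  slice <- dplyr::inner_join(
    dplyr::filter(waves, .data$year %in% .env$years),
    depths, by = c("row", "col")
  )
  hmax <- cap_breaking(hmax_from_hm0(slice$hm0, constants), slice$depth)
  t_use <- if (period == "thmax") {
    thmax_from_hmax(hmax, constants)
  } else {
    slice$tm02
  }
  slice$mov <- bottom_orbital_velocity(hmax, t_use, slice$depth,
                                       g = constants$g)
  agg <- if (statistic == "mean") {
    function(x) mean(x)
  } else {
    function(x) as.numeric(quantile(x, probs))
  }
  out <- dplyr::summarise(
    dplyr::group_by(slice, .data$row, .data$col),
    mov = agg(.data$mov), .groups = "drop"
  )
  dplyr::arrange(out, .data$row, .data$col)
}
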