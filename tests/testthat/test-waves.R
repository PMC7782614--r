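test_that("the Rayleigh maximum-wave factor matches its closed form", {
  expect_equal(wave_constants()$hmax_factor, 1.86)
  expect_equal(round(sqrt(log(1000) / 2), 2), 1.86)
  expect_error(wave_constants(n_waves = 100), "inconsistent")
})

test_that("maximum wave height and period follow the empirical relations", {
  expect_equal(hmax_from_hm0(1), 1.86)
  expect_equal(hmax_from_hm0(0), 0)
  expect_equal(hmax_from_hm0(2), 3.72)
  expect_equal(thmax_from_hmax(0), 3.17)
  expect_equal(thmax_from_hmax(1), 4.00)
  expect_equal(thmax_from_hmax(1.86), 4.7138)
  expect_error(hmax_from_hm0(-0.1))
  expect_error(thmax_from_hmax(-0.1))
})

test_that("breaking caps the maximum wave at the local depth", {
  expect_equal(cap_breaking(3.72, 2), 2)
  expect_equal(cap_breaking(0.5, 2), 0.5)
  expect_equal(cap_breaking(2, 2), 2)
  expect_error(cap_breaking(1, 0), "d")
})

test_that("dispersion solutions satisfy the defining equation everywhere", {
  set.seed(42)
  t <- runif(1000, 1, 15)
  d <- runif(1000, 0.05, 300)
  l <- dispersion_wavelength(t, d)
  l0 <- 9.81 * t^2 / (2 * pi)
  residual <- abs(l0 * tanh(2 * pi * d / l) - l)
  expect_true(all(residual < 1e-6))
  expect_true(all(l > 0 & l <= l0 + 1e-9))
})

test_that("dispersion attains the deep- and shallow-water limits", {
  # deep: L -> g t^2 / 2 pi
  expect_equal(dispersion_wavelength(10, 1000), 9.81 * 100 / (2 * pi),
               tolerance = 1e-3)
  # shallow: L -> t sqrt(g d), within 1%
  expect_equal(dispersion_wavelength(5, 0.1), 5 * sqrt(9.81 * 0.1),
               tolerance = 0.01)
})

test_that("dispersion agrees with an independent bisection oracle", {
  bisect <- function(t, d) {
    l0 <- 9.81 * t^2 / (2 * pi)
    f <- function(l) l0 * tanh(2 * pi * d / l) - l
    lo <- 1e-4
    hi <- l0 + 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  set.seed(7)
  for (i in 1:25) {
    t <- runif(1, 2, 12)
    d <- runif(1, 0.2, 60)
    expect_equal(dispersion_wavelength(t, d), bisect(t, d),
                 tolerance = 1e-6)
  }
})

test_that("bottom orbital velocity matches hand-checked values and limits", {
  expect_equal(bottom_orbital_velocity(0, 5, 2), 0)
  # independent chain: bisection wavelength then the direct formula
  l <- dispersion_wavelength(5, 2)
  expect_equal(l, 20.96, tolerance = 1e-3)
  expect_equal(bottom_orbital_velocity(1, 5, 2),
               pi * 1 / (5 * sinh(2 * pi * 2 / l)))
  expect_equal(round(bottom_orbital_velocity(1, 5, 2), 2), 0.99)
  # deep water: exponentially small at the bed
  expect_lt(bottom_orbital_velocity(1, 5, 100), 1e-3)
})

test_that("orbital velocity is linear in wave height below breaking", {
  u1 <- bottom_orbital_velocity(0.4, 4, 6)
  u2 <- bottom_orbital_velocity(0.8, 4, 6)
  expect_equal(u2, 2 * u1)
})

test_that("the MOV field equals the scalar chain cell by cell", {
  grid <- tiny_grid()
  w <- make_wave_series(grid, "B1_2", years = 2007:2008, seed = 3)
  field <- mov_predictor_field(w, grid, 2007:2008)
  cells <- dplyr::inner_join(
    w, dplyr::select(dplyr::filter(grid, in_scope), row, col, depth),
    by = c("row", "col")
  )
  hmax <- cap_breaking(hmax_from_hm0(cells$hm0), cells$depth)
  cells$u <- bottom_orbital_velocity(hmax, thmax_from_hmax(hmax),
                                     cells$depth)
  manual <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(cells, row, col), mov = mean(u),
                     .groups = "drop"),
    row, col
  )
  expect_equal(field$mov, manual$mov)
})

test_that("identical yearly sea states collapse to the single-year field", {
  grid <- tiny_grid()
  w <- make_wave_series(grid, "A1B_2", years = 2007:2011,
                        trends = c(A1B_1 = 0, A1B_2 = 0, B1_1 = 0, B1_2 = 0),
                        year_noise_sd = 0, seed = 1)
  slice <- mov_predictor_field(w, grid, 2007:2011)
  single <- mov_predictor_field(w, grid, 2007)
  expect_equal(slice$mov, single$mov)
  # H_m0 = 0 everywhere -> MOV identically zero
  w0 <- dplyr::mutate(w, hm0 = 0)
  expect_equal(unique(mov_predictor_field(w0, grid, 2007:2011)$mov), 0)
})

test_that("MOV declines with depth beyond the breaking-cap zone", {
  grid <- make_bathymetry(n_rows = 40, n_cols = 1, slope = 0.3,
                          bay_amplitude = 0, roughness = 0, seed = 1)
  w <- make_wave_series(grid, "A1B_1", years = 2007, year_noise_sd = 0,
                        alongshore_amplitude = 0, seed = 1)
  transect <- dplyr::inner_join(mov_predictor_field(w, grid, 2007),
                                grid, by = c("row", "col"))
  uncapped <- transect$depth > hmax_from_hm0(max(w$hm0))
  expect_monotone(transect$mov[uncapped], "decreasing", tol_frac = 0)
})

test_that("the tm02 sensitivity path uses the sea-state period", {
  grid <- tiny_grid()
  w <- make_wave_series(grid, "B1_1", years = 2007, seed = 2)
  default <- mov_predictor_field(w, grid, 2007)
  alt <- mov_predictor_field(w, grid, 2007, period = "tm02")
  expect_false(isTRUE(all.equal(default$mov, alt$mov)))
})
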