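test_that("noise-free BAU Secchi without oscillation is constant in time", {
  grid <- tiny_grid()
  sd <- make_secchi_series(grid, "BAU", years = 2007:2030, oscillation = 0,
                           year_noise_sd = 0, cell_noise_sd = 0, seed = 1)
  expect_equal(unique(sd$secchi), 5)
})

test_that("BSAP improvement ramps linearly over 2012-2020 and plateaus", {
  grid <- tiny_grid()
  sd <- make_secchi_series(grid, "BSAP", years = 2007:2030, improvement = 2,
                           year_noise_sd = 0, cell_noise_sd = 0, seed = 1)
  by_year <- dplyr::distinct(sd, year, secchi)
  v <- function(y) by_year$secchi[by_year$year == y]
  expect_equal(v(2021) - v(2011), 2)
  expect_equal(v(2030) - v(2011), 2)
  expect_equal(v(2016) - v(2011), 1) # halfway through the ramp
  # one plateau value per year from 2021 on
  expect_equal(nrow(by_year), length(2007:2030))
})

test_that("default BSAP clarity improves at every in-scope cell", {
  grid <- tiny_grid()
  sd <- make_secchi_series(grid, "BSAP", years = c(2007:2011, 2062:2066),
                           seed = 1)
  early <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(sd, year <= 2011), row, col),
    m = mean(secchi), .groups = "drop"
  )
  late <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(sd, year >= 2062), row, col),
    m = mean(secchi), .groups = "drop"
  )
  expect_true(all(late$m > early$m))
})

test_that("nutrient scenarios share identical pre-divergence years", {
  grid <- tiny_grid()
  bsap <- make_secchi_series(grid, "BSAP", years = 2007:2013, seed = 4)
  bau <- make_secchi_series(grid, "BAU", years = 2007:2013, oscillation = 0,
                            seed = 4)
  expect_equal(bsap$secchi[bsap$year <= 2011], bau$secchi[bau$year <= 2011])
})

test_that("trend-free noise-free sea state is identical across years", {
  grid <- tiny_grid()
  w <- make_wave_series(grid, "A1B_1", years = 2007:2012,
                        trends = c(A1B_1 = 0, A1B_2 = 0, B1_1 = 0, B1_2 = 0),
                        year_noise_sd = 0, seed = 1)
  per_year <- split(w$hm0, w$year)
  for (y in per_year) expect_equal(y, per_year[[1]])
  expect_equal(w$tm02, 2.6 + 1.6 * w$hm0)
})

test_that("a positive trend makes the yearly mean sea state increase", {
  grid <- tiny_grid()
  w <- make_wave_series(grid, "B1_1", years = 2007:2020,
                        trends = c(A1B_1 = 0, A1B_2 = 0, B1_1 = 0.01,
                                   B1_2 = 0),
                        year_noise_sd = 0, seed = 1)
  means <- tapply(w$hm0, w$year, mean)
  expect_true(all(diff(means) > 0))
})

test_that("realizations differ while sharing the coastline exposure pattern", {
  grid <- tiny_grid()
  a <- make_wave_series(grid, "A1B_1", years = 2007:2010, seed = 2)
  b <- make_wave_series(grid, "B1_1", years = 2007:2010, seed = 2)
  expect_false(identical(a$hm0, b$hm0))
  # first year, zero trend elapsed: only the interannual noise factor
  # differs, so the spatial pattern is proportional
  a1 <- a$hm0[a$year == 2007]
  b1 <- b$hm0[b$year == 2007]
  expect_equal(stats::cor(a1, b1), 1)
})

test_that("scenario fields exist only for in-scope cells", {
  grid <- make_bathymetry(n_rows = 15, n_cols = 6, slope = 1,
                          bay_amplitude = 0, roughness = 0, seed = 1)
  sd <- make_secchi_series(grid, "BAU", years = 2007:2008, seed = 1)
  w <- make_wave_series(grid, "B1_2", years = 2007:2008, seed = 1)
  in_scope <- dplyr::filter(grid, in_scope)
  for (f in list(sd, w)) {
    cells <- dplyr::distinct(f, row, col)
    expect_equal(nrow(cells), nrow(in_scope))
    expect_true(all(cells$row <= 12))
  }
})

test_that("unknown scenario labels are rejected", {
  grid <- tiny_grid()
  expect_error(make_secchi_series(grid, "BSAP2"))
  expect_error(make_wave_series(grid, "A2"))
  expect_error(make_secchi_series(grid, "BAU", years = 2000:2010), "2007")
})
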