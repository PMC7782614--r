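test_that("Secchi-to-attenuation conversion follows the reciprocal law", {
  expect_equal(attenuation_from_secchi(1.7), 1.0)
  expect_equal(attenuation_from_secchi(8.5), 0.2)
  expect_equal(attenuation_from_secchi(c(1.7, 3.4)), c(1.0, 0.5))
  expect_error(attenuation_from_secchi(0), "Secchi")
  expect_error(attenuation_from_secchi(-2), "Secchi")
})

test_that("irradiance converts to PFD with the 4.15 factor", {
  expect_equal(pfd_surface(1), 4.15)
  expect_equal(pfd_surface(0), 0)
  expect_equal(pfd_surface(100), 415)
  expect_error(pfd_surface(-1), "Irradiance")
})

test_that("canopy PFD follows Beer's law with the 0.5 m offset", {
  # k = 0.5, d = 2.5 -> z = 2: one full e-folding
  expect_equal(pfd_at_canopy(415, 0.5, 2.5), 415 * exp(-1))
  expect_equal(pfd_at_canopy(415, 0, 7), 415) # no attenuation
  expect_equal(pfd_at_canopy(415, 3, 0.5), 415) # z clamps to 0
  expect_equal(pfd_at_canopy(415, 3, 0.2), 415) # shallower than the offset
  expect_error(pfd_at_canopy(415, 0.5, 0), "land")
  expect_error(pfd_at_canopy(-1, 0.5, 1))
})

test_that("canopy PFD is monotone in depth, attenuation and clarity", {
  i0 <- pfd_surface(120)
  depths <- seq(0.6, 12, by = 0.2)
  expect_monotone(pfd_at_canopy(i0, 0.4, depths), "decreasing", tol_frac = 0)
  ks <- seq(0.1, 2, by = 0.1)
  expect_monotone(pfd_at_canopy(i0, ks, 5), "decreasing", tol_frac = 0)
  sds <- seq(1, 10, by = 0.5)
  expect_monotone(
    pfd_at_canopy(i0, attenuation_from_secchi(sds), 5),
    "increasing", tol_frac = 0
  )
})

test_that("field computation equals the scalar chain cell by cell", {
  grid <- tiny_grid()
  sd <- make_secchi_series(grid, "BAU", years = 2007:2011, oscillation = 0,
                           year_noise_sd = 0, cell_noise_sd = 0, seed = 1)
  field <- pfd_predictor_field(sd, grid, 2007:2011)
  cells <- dplyr::inner_join(field, dplyr::filter(grid, in_scope),
                             by = c("row", "col"))
  i0 <- mean(pfd_surface(irradiance_climatology()$irradiance))
  expect_equal(
    cells$pfd,
    pfd_at_canopy(i0, attenuation_from_secchi(5), cells$depth)
  )
})

test_that("doubling water clarity raises PFD wherever light attenuates", {
  grid <- tiny_grid()
  years <- 2007:2011
  sd1 <- make_secchi_series(grid, "BAU", years = years, oscillation = 0,
                            year_noise_sd = 0, cell_noise_sd = 0, seed = 1)
  sd2 <- dplyr::mutate(sd1, secchi = secchi * 2)
  f1 <- pfd_predictor_field(sd1, grid, years)
  f2 <- pfd_predictor_field(sd2, grid, years)
  depth <- dplyr::inner_join(f1, grid, by = c("row", "col"))$depth
  improving <- depth > 0.5
  expect_true(all(f2$pfd[improving] > f1$pfd[improving]))
  expect_equal(f2$pfd[!improving], f1$pfd[!improving])
})

test_that("a slice mean lies between the first and last yearly field", {
  grid <- tiny_grid()
  years <- 2012:2016
  sd <- make_secchi_series(grid, "BSAP", years = years, improvement = 2,
                           year_noise_sd = 0, cell_noise_sd = 0, seed = 1)
  slice <- pfd_predictor_field(sd, grid, years)
  lo <- pfd_predictor_field(sd, grid, 2012)
  hi <- pfd_predictor_field(sd, grid, 2016)
  expect_true(all(slice$pfd >= lo$pfd - 1e-12))
  expect_true(all(slice$pfd <= hi$pfd + 1e-12))
})

test_that("missing slice years are reported", {
  grid <- tiny_grid()
  sd <- make_secchi_series(grid, "BAU", years = 2007:2009, seed = 1)
  expect_error(pfd_predictor_field(sd, grid, 2007:2011), "2010")
})

test_that("irradiance climatology round-trips through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  clim <- irradiance_climatology()
  utils::write.csv(clim, path, row.names = FALSE)
  expect_equal(read_irradiance(path), clim)
})
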