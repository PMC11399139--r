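test_that("soil heat flux ratio matches hand evaluations and clips", {
  g <- soil_heat_flux(matrix(500), matrix(293.15), matrix(0.2),
                      matrix(0.7))
  expect_equal(attr(g, "ratio")[1, 1], 0.0808, tolerance = 5e-4 / 0.08)
  expect_equal(g[1, 1], 40.4, tolerance = 0.3 / 40)
  # zero Celsius surface -> zero flux
  expect_equal(soil_heat_flux(matrix(500), matrix(273.15), matrix(0.2),
                              matrix(0.7))[1, 1], 0)
  # full canopy: the (1 - 0.98 NDVI^4) factor nearly closes G
  g1 <- soil_heat_flux(matrix(500), matrix(293.15), matrix(0.2),
                       matrix(1))
  expect_equal(attr(g1, "ratio")[1, 1], 0.00211, tolerance = 1e-4 / 0.002)
  # zero albedo pixel is a guarded nodata
  expect_true(is.na(soil_heat_flux(matrix(500), matrix(293.15),
                                   matrix(0), matrix(0.5))[1, 1]))
})

test_that("G/Rn stays in [0, 0.5] and realistic crops in [0.002, 0.25]", {
  set.seed(21)
  n <- 2000
  ts <- matrix(runif(n, 283.15, 308.15), 1)   # 10-35 C
  alb <- matrix(runif(n, 0.1, 0.3), 1)
  nd <- matrix(runif(n, 0.3, 0.9), 1)
  g <- soil_heat_flux(matrix(500, 1, n), ts, alb, nd)
  ratio <- attr(g, "ratio")
  expect_true(all(ratio >= 0 & ratio <= 0.5))
  expect_true(all(ratio >= 0.002 & ratio <= 0.25))
})

test_that("latent heat flux: hand value, zero cases, clipping count", {
  le <- latent_heat_flux(matrix(1.26), matrix(550), matrix(50),
                         0.1887, 0.0674)
  expect_equal(le[1, 1], 464.3, tolerance = 1 / 464)
  expect_equal(latent_heat_flux(matrix(0), matrix(500), matrix(50),
                                0.19, 0.067)[1, 1], 0)
  neg <- latent_heat_flux(matrix(1), matrix(10), matrix(50), 0.19, 0.067)
  expect_equal(neg[1, 1], 0)
  expect_equal(attr(neg, "n_clipped"), 1L)
  expect_error(latent_heat_flux(matrix(1), matrix(500), matrix(50),
                                -0.1, 0.067), "positive")
})

test_that("instantaneous ET converts W/m^2 to mm/h linearly", {
  expect_equal(instantaneous_et(matrix(500))[1, 1], 0.7347,
               tolerance = 1e-3 / 0.73)
  expect_equal(instantaneous_et(matrix(0))[1, 1], 0)
  le <- matrix(runif(10, 0, 600), 1)
  expect_equal(instantaneous_et(2 * le), 2 * instantaneous_et(le))
})

test_that("evaporative fraction: identity with phi, nodata guard", {
  le <- latent_heat_flux(matrix(1.26), matrix(500), matrix(0),
                         0.1887, 0.0674)
  ef <- evaporative_fraction(le, matrix(500), matrix(0))
  expect_equal(ef[1, 1], 1.26 * 0.1887 / (0.1887 + 0.0674),
               tolerance = 1e-12)
  # LE = available energy -> EF 1
  expect_equal(evaporative_fraction(matrix(450), matrix(500),
                                    matrix(50))[1, 1], 1)
  bad <- evaporative_fraction(matrix(0), matrix(10), matrix(50))
  expect_true(is.na(bad[1, 1]))
  expect_equal(attr(bad, "n_invalid"), 1L)
})

test_that("daylight length is sane for the study latitudes", {
  n_winter <- daylight_hours(29, 351)
  n_summer <- daylight_hours(29, 172)
  expect_lt(n_winter, 12); expect_gt(n_winter, 8)
  expect_gt(n_summer, 12); expect_lt(n_summer, 16)
  expect_equal(daylight_hours(0, 100), 12, tolerance = 1e-6)
})

test_that("half-sine daily energy: closed form at noon, off-noon factor", {
  e <- daily_available_energy(matrix(500), matrix(0), 12, 12)
  expect_equal(e[1, 1], 13.75, tolerance = 0.01 / 13.75)
  # overpass at 10:30, sunrise 06:00: peak = obs / sin(pi 4.5/12)
  e2 <- daily_available_energy(matrix(500), matrix(0), 10.5, 12)
  expect_equal(e2[1, 1] / e[1, 1], 1 / sin(pi * 4.5 / 12),
               tolerance = 1e-9)
  expect_equal(1 / sin(pi * 4.5 / 12), 1 / 0.9239, tolerance = 1e-4)
  expect_error(daily_available_energy(matrix(500), matrix(0), 19, 12),
               "daylight")
  # user-supplied pass-through
  u <- matrix(7.3)
  expect_identical(daily_available_energy(matrix(1), matrix(0), 12, 12,
                                          mode = "user_supplied",
                                          user_energy = u), u)
})

test_that("daily ET: hand value, zero and linear in the coefficient", {
  expect_equal(daily_et(matrix(0.7), matrix(10), 1.1)[1, 1], 3.143,
               tolerance = 5e-3 / 3.14)
  expect_equal(daily_et(matrix(0), matrix(10))[1, 1], 0)
  expect_equal(daily_et(matrix(0.5), matrix(8), 2.2),
               2 * daily_et(matrix(0.5), matrix(8), 1.1))
})

test_that("half-sine ETi integral equals ETd / alpha for constant EF", {
  ef <- 0.65; rn_g <- 480; n_day <- 11.2; overpass <- 10.4
  e_d <- daily_available_energy(matrix(rn_g), matrix(0), overpass, n_day)
  et_d <- daily_et(matrix(ef), e_d, 1.1)
  # numeric integral of ETi(t) = 3600 EF E(t) / 2.45e6 over daylight
  sunrise <- 12 - n_day / 2
  e_peak <- rn_g / sin(pi * (overpass - sunrise) / n_day)
  et_int <- stats::integrate(function(t)
    ef * e_peak * sin(pi * (t - sunrise) / n_day) * 3600 / 2.45e6,
    sunrise, sunrise + n_day, rel.tol = 1e-10)$value
  expect_equal(et_int, et_d[1, 1] / 1.1, tolerance = 1e-6)
})
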