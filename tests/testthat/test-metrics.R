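test_that("roughness: constants, the 1..9 window, and invariances", {
  ext <- c(0, 5, 0, 5)
  flat <- ovd_raster(matrix(7, 5, 5), ext)
  expect_true(all(terrain_roughness(flat)$values == 0))

  v <- matrix(0, 5, 5)
  v[2:4, 2:4] <- matrix(1:9, 3, 3)
  r <- terrain_roughness(ovd_raster(v, ext))
  expect_identical(r$values[3, 3], 9 - 1)

  set.seed(50)
  v2 <- matrix(rnorm(100), 10, 10)
  r2 <- terrain_roughness(ovd_raster(v2, c(0, 10, 0, 10)))
  # translation invariance and linear scaling
  r2b <- terrain_roughness(ovd_raster(v2 + 100, c(0, 10, 0, 10)))
  expect_equal(r2$values, r2b$values, tolerance = 1e-12)
  r2c <- terrain_roughness(ovd_raster(3 * v2, c(0, 10, 0, 10)))
  expect_equal(r2c$values, 3 * r2$values, tolerance = 1e-12)
  # nodata propagates at the focal cell
  v2[4, 4] <- NA
  expect_true(is.na(terrain_roughness(
    ovd_raster(v2, c(0, 10, 0, 10)))$values[4, 4]))
  expect_error(terrain_roughness(ovd_raster(matrix(NA_real_, 4, 4),
                                            c(0, 4, 0, 4))), "valid")
})

test_that("roughness equals the window-scan oracle on random DEMs", {
  set.seed(51)
  for (rep in 1:5) {
    v <- matrix(rnorm(2500, 500, 150), 50, 50)
    r <- terrain_roughness(ovd_raster(v, c(0, 50, 0, 50)))
    expect_equal(r$values, roughness_oracle(v), tolerance = 1e-12)
  }
})

test_that("geometry classification follows the published rule order", {
  set.seed(52)
  # strongly right-skewed unimodal: pyramid
  pyr <- classify_geometry(rbeta(200, 1.5, 8) * 2000)
  expect_identical(pyr$class, "pyramid")
  expect_gte(pyr$skewness, 0.5)
  # mirrored: inverse pyramid
  expect_identical(classify_geometry(rbeta(200, 8, 1.5) * 2000)$class,
                   "inverse_pyramid")
  # symmetric unimodal: diamond
  dia <- classify_geometry(rbeta(200, 6, 6) * 2000)
  expect_identical(dia$class, "diamond")
  expect_lt(abs(dia$skewness), 0.5)
  # bimodal with positive skew: hourglass wins irrespective of skewness
  skewed_bim <- c(rbeta(160, 3, 18), rbeta(80, 18, 3)) * 2000
  cb <- classify_geometry(skewed_bim)
  expect_true(cb$dip > 0.01 && cb$p_dip < 0.05)
  expect_identical(cb$class, "hourglass")
  expect_error(classify_geometry(rnorm(10)), "refused")
})

test_that("gVoCC: closed form, zero trend, sign and monotonicity", {
  s <- simulate_climate_series(trend = 0.02, spatial_gradient = 0.01,
                               noise_sd = 0, years = 12, seed = 1,
                               extent = c(0, 8, 10, 18), res = 1)
  v <- gvocc(s)
  expect_lt(max(abs(v$velocity$values - 2)), 1e-6)
  expect_lt(max(abs(v$trend$values - 0.02)), 1e-12)
  expect_lt(max(abs(v$gradient$values - 0.01)), 1e-9)

  s0 <- simulate_climate_series(trend = 0, spatial_gradient = 0.01,
                                noise_sd = 0, years = 12, seed = 1,
                                extent = c(0, 8, 10, 18), res = 1)
  expect_lt(max(abs(gvocc(s0)$velocity$values)), 1e-12)

  # cooling trend gives negative velocity; steeper gradient shrinks |v|
  sm <- simulate_climate_series(trend = -0.02, spatial_gradient = 0.02,
                                noise_sd = 0, years = 12, seed = 1,
                                extent = c(0, 8, 10, 18), res = 1)
  vm <- gvocc(sm)$velocity$values
  expect_true(all(vm < 0))
  expect_lt(max(abs(vm)), 2)
  # a flat field is everywhere undefined, not infinite
  sf <- simulate_climate_series(trend = 0.02, spatial_gradient = 0,
                                noise_sd = 0, years = 12, seed = 1,
                                extent = c(0, 8, 10, 18), res = 1)
  expect_true(all(is.na(gvocc(sf)$velocity$values)))
  expect_error(gvocc(simulate_climate_series(years = 3, seed = 1,
                                             extent = c(0, 4, 0, 4), res = 1)),
               "10 years")
})

test_that("predictor extraction: constants, distances, zonal oracle", {
  w <- small_world()
  ids <- names(w$mountains$geoms)[1:4]
  mts <- ovd_layer(w$mountains$geoms[ids],
                   w$mountains$data[1:4, , drop = FALSE])
  ext <- w$config$grid_extent
  const <- ovd_raster(matrix(3.5, nrow(w$dem$values), ncol(w$dem$values)), ext)
  rasters <- list(pop_density = const, road_density = const,
                  bii = const, completeness = const)
  vel <- gvocc(w$climate)
  # a city inside the first mountain polygon gives distance zero
  ctr <- colMeans(mts$geoms[[1]])
  cities <- data.frame(city_id = "c1", lon = ctr[1], lat = ctr[2])
  pred <- extract_predictors(mts, rasters, w$dem, vel$velocity,
                             cities, w$ports)
  expect_true(all(pred$pop_density == 3.5))
  expect_identical(pred$dist_cities[1], 0)
  expect_true(all(pred$dist_cities[-1] > 0))
  expect_equal(pred$elev_range,
               mts$data$elev_max - mts$data$elev_min, tolerance = 1e-12)
  # zonal means against the exhaustive oracle
  for (i in 1:2)
    expect_equal(pred$roughness[i],
                 zonal_oracle(terrain_roughness(w$dem), mts$geoms[[i]]),
                 tolerance = 1e-9)
  # geometry classes recover the generator's truth for these mountains
  truth <- w$truth$geometry[pred$mountain_id]
  ok <- !is.na(pred$geometry)
  expect_gte(mean(pred$geometry[ok] == truth[ok]), 0.5)
})
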