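test_that("config invariants are enforced", {
  expect_error(world_config(n_realms = 0), "counts")
  expect_error(world_config(taxon_class_weights = c(fish = 1)), "named")
  expect_error(world_config(grid_extent = c(0, 0, 0, 10)), "degenerate")
  w <- world_config(taxon_class_weights = c(fish = .2, amphibian = .2,
                                            reptile = .2, bird = .2,
                                            mammal = .2))
  expect_equal(sum(w$taxon_class_weights), 1)
})

test_that("same seed gives identical worlds; mountains are disjoint", {
  cfg <- world_config(n_mountains = 12, n_species_pool = 40, seed = 5)
  w1 <- suppressWarnings(generate_world(cfg))
  w2 <- suppressWarnings(generate_world(cfg))
  w1$config <- w2$config <- NULL
  expect_identical(w1, w2)
  w1 <- suppressWarnings(generate_world(cfg))
  expect_length(find_overlapping_pairs(w1$mountains), 0)
  expect_true(all(w1$mountains$data$elev_max >= w1$mountains$data$elev_min))
  expect_true(all(w1$mountains$data$area_km2 > 0))
})

test_that("one realm means every species is native to it", {
  w <- suppressWarnings(generate_world(
    world_config(n_realms = 1, n_mountains = 8, n_species_pool = 30,
                 seed = 9)))
  expect_true(all(vapply(w$species, function(s)
    identical(s$native_realms, "R01"), TRUE)))
})

test_that("occurrence mixture: conservation and the alien fraction", {
  w <- small_world()
  tr <- w$truth$records
  expect_identical(nrow(tr), nrow(w$occurrences))
  expect_identical(sum(tr$true_alien) + sum(!tr$true_alien), nrow(tr))
  # all records inside the grid extent
  ext <- w$config$grid_extent
  expect_true(all(tr$lon >= ext[1] & tr$lon <= ext[2] &
                  tr$lat >= ext[3] & tr$lat <= ext[4]))

  occ0 <- simulate_occurrences(w, alien_fraction = 0, seed = 1)
  expect_identical(sum(occ0$truth$true_alien), 0L)
  occ1 <- suppressWarnings(simulate_occurrences(w, alien_fraction = 1, seed = 1))
  expect_identical(sum(!occ1$truth$true_alien), 0L)
  # mixture 0.5: empirical share within a binomial 99% CI
  occ5 <- suppressWarnings(
    simulate_occurrences(w, alien_fraction = 0.5, records_per_species = 50,
                         seed = 2))
  n <- nrow(occ5$truth)
  expect_lt(abs(mean(occ5$truth$true_alien) - 0.5),
            qnorm(0.995) * sqrt(0.25 / n) + 0.01)
})

test_that("NB count simulation: mean/area, monotonicity, mean-variance", {
  set.seed(77)
  n <- 5000
  d0 <- data.frame(x = rnorm(n),
                   continent_id = "C1", region_id = "G1",
                   system_id = sprintf("S%d", sample(20, n, TRUE)),
                   area_km2 = exp(runif(n, 2, 6)))
  # beta = 0, sigma = 0, huge theta: counts ~ Poisson(area)
  d <- simulate_richness_counts(d0, c("(Intercept)" = 0, x = 0), theta = 1e6,
                                sigma = c(continent = 0, region = 0,
                                          system = 0), seed = 1)
  expect_lt(abs(mean(d$n_species / d$area_km2) - 1), 0.05)

  # raising a positive coefficient raises counts generated from the same seed
  d_lo <- simulate_richness_counts(d0, c("(Intercept)" = -2, x = 0.2),
                                   theta = 2, sigma = c(continent = 0,
                                                        region = 0, system = 0),
                                   seed = 3)
  d_hi <- simulate_richness_counts(d0, c("(Intercept)" = -2, x = 0.4),
                                   theta = 2, sigma = c(continent = 0,
                                                        region = 0, system = 0),
                                   seed = 3)
  hi_x <- d0$x > 1
  expect_gt(mean(d_hi$n_species[hi_x]), mean(d_lo$n_species[hi_x]))

  # NB mean-variance: Var ~ mu + mu^2/theta at fixed mu
  d0$area_km2 <- 100
  dd <- simulate_richness_counts(d0, c("(Intercept)" = -3), theta = 2,
                                 sigma = c(continent = 0, region = 0,
                                           system = 0), seed = 4)
  mu <- 100 * exp(-3)
  expect_lt(abs(var(dd$n_species) / (mu + mu^2 / 2) - 1), 0.15)

  # system-level clustering beats a shuffled baseline
  ds <- simulate_richness_counts(d0, c("(Intercept)" = -3), theta = 10,
                                 sigma = c(continent = 0, region = 0,
                                           system = 1), seed = 5)
  icc <- function(y, g) {
    m <- tapply(y, g, mean)
    var(m[g]) / var(y)
  }
  y <- log1p(ds$n_species)
  obs <- icc(y, ds$system_id)
  set.seed(6)
  null <- replicate(200, icc(y, sample(ds$system_id)))
  expect_gt(obs, quantile(null, 0.99))

  expect_error(simulate_richness_counts(
    transform(d0, x = c(Inf, rep(0, n - 1))),
    c("(Intercept)" = 0, x = 1), theta = 2,
    sigma = c(continent = 0, region = 0, system = 0), seed = 1),
    "row")
})

test_that("climate series: construction, flatness, and per-cell OLS slopes", {
  expect_error(simulate_climate_series(years = 1), "years")
  flat <- simulate_climate_series(trend = 0, noise_sd = 0, years = 3, seed = 1,
                                  extent = c(0, 4, 0, 4), res = 1)
  expect_equal(max(apply(flat$values, c(1, 2), sd)), 0)

  s <- simulate_climate_series(trend = 0.02, noise_sd = 0.3, years = 30,
                               seed = 10, extent = c(0, 6, 0, 6), res = 1)
  years <- sort(unique(s$year))
  ty <- years - mean(years)
  for (cell in list(c(1, 1), c(3, 4), c(6, 6))) {
    ann <- vapply(years, function(yy)
      mean(s$values[cell[1], cell[2], s$year == yy]), 0)
    b <- sum(ty * ann) / sum(ty^2)
    se <- sqrt(sum(resid(lm(ann ~ ty))^2) / (length(ty) - 2) / sum(ty^2))
    expect_lt(abs(b - 0.02), 3 * se)
  }
})

test_that("a written world round-trips through the external formats", {
  w <- small_world()
  dir <- file.path(tempdir(), "wtest")
  write_world(w, dir)
  expect_true(all(file.exists(file.path(dir,
    c("realms.geojson", "mountains.geojson", "occurrences.csv", "dem.asc",
      "climate_tmin.csv", "ground_truth.json", "native_ranges.geojson")))))
  rg <- read_ranges_geojson(file.path(dir, "native_ranges.geojson"))
  expect_identical(length(rg), length(w$species))
  expect_equal(rg[[3]]$native_polygons[[1]],
               w$species[[3]]$native_polygons[[1]], tolerance = 1e-12)
})
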