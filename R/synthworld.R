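# Synthetic world generator.
#
# Produces a self-contained, seeded world -- biogeographic realms, disjoint
# convex mountain polygons nested in a system < region < continent hierarchy,
# a DEM whose within-mountain elevation distributions force known geometry
# classes, anthropogenic predictor rasters, a monthly minimum-temperature
# series with known trend and spatial gradient, species with convex native
# ranges, a native/alien mixture of occurrence records, and protected areas --
# together with the ground truth needed to test every downstream stage.

#' Configuration for the synthetic world
#'
#' Defaults give a reduced-scale world with the structure of the real data:
#' five vertebrate classes weighted like the global alien pool, six
#' biogeographic realms, and mountains large enough (>= 30 raster cells) for
#' elevation-distribution classification.
#'
#' @param n_realms number of biogeographic realms (Voronoi tiles).
#' @param n_mountains number of disjoint mountain polygons.
#' @param n_species_pool number of species in the global pool.
#' @param taxon_class_weights named proportions over the five classes,
#'   summing to 1.
#' @param grid_extent numeric length 4 (xmin, xmax, ymin, ymax), degrees.
#' @param raster_resolution cell size in degrees of the DEM and predictor
#'   rasters.
#' @param climate_resolution cell size in degrees of the monthly temperature
#'   stack (coarser, like the real climate time series).
#' @param seed integer root seed; all stages derive named sub-streams.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_realms = 6,
                         n_mountains = 100,
                         n_species_pool = 800,
                         taxon_class_weights = c(fish = 0.14, amphibian = 0.08,
                                                 reptile = 0.11, bird = 0.44,
                                                 mammal = 0.23),
                         grid_extent = c(0, 40, 5, 45),
                         raster_resolution = 0.25,
                         climate_resolution = 0.5,
                         seed = 1L) {
  if (any(c(n_realms, n_mountains, n_species_pool) < 1))
    stop_oro("configuration error: all counts must be >= 1")
  if (!setequal(names(taxon_class_weights), TAXON_CLASSES))
    stop_oro("taxon_class_weights must be named over: ",
             paste(TAXON_CLASSES, collapse = ", "))
  taxon_class_weights <- taxon_class_weights[TAXON_CLASSES]
  if (abs(sum(taxon_class_weights) - 1) > 1e-9)
    stop_oro("configuration error: taxon_class_weights must sum to 1")
  if (length(grid_extent) != 4 ||
      grid_extent[2] <= grid_extent[1] || grid_extent[4] <= grid_extent[3])
    stop_oro("configuration error: degenerate grid extent")
  if (raster_resolution <= 0 || climate_resolution <= 0)
    stop_oro("raster resolutions must be > 0")
  structure(list(n_realms = as.integer(n_realms),
                 n_mountains = as.integer(n_mountains),
                 n_species_pool = as.integer(n_species_pool),
                 taxon_class_weights = taxon_class_weights,
                 grid_extent = as.numeric(grid_extent),
                 raster_resolution = raster_resolution,
                 climate_resolution = climate_resolution,
                 seed = as.integer(seed)),
            class = "world_config")
}

GEOMETRY_CLASSES <- c("pyramid", "inverse_pyramid", "diamond", "hourglass")

# relative elevation draws whose skew/modality force each geometry class
draw_class_elevations <- function(class, n) {
  # parameters chosen so the intended class is forced with high probability
  # at the cell counts mountains actually have (moment skewness +-1.06 for
  # the pyramids, 0 for diamond; well-separated modes for hourglass)
  switch(class,
    pyramid = rbeta(n, 1.5, 8),
    inverse_pyramid = rbeta(n, 8, 1.5),
    diamond = rbeta(n, 6, 6),
    hourglass = {
      lo <- stats::rbinom(n, 1, 0.5) == 1
      ifelse(lo, rbeta(n, 3, 18), rbeta(n, 18, 3))
    },
    stop_oro("unknown geometry class: ", class))
}

# smooth random field over cell centers: sum of k random plane waves
smooth_field <- function(xc, yc, k = 6, lambda_range = NULL) {
  span <- max(diff(range(xc)), diff(range(yc)))
  lambda_range <- lambda_range %||% c(span / 6, span)
  f <- matrix(0, length(yc), length(xc))
  for (j in seq_len(k)) {
    lambda <- runif(1, lambda_range[1], lambda_range[2])
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    u <- cos(th) / lambda; v <- sin(th) / lambda
    f <- f + outer(yc, xc, function(y, x) cos(2 * pi * (u * x + v * y) + ph))
  }
  f / sqrt(k)
}

sample_point_in_polygon <- function(poly, n, max_tries = 2000) {
  # batched bounding-box rejection
  out <- matrix(numeric(0), 0, 2)
  bb <- c(range(poly[, 1]), range(poly[, 2]))
  tries <- 0
  while (nrow(out) < n && tries < max_tries) {
    m <- max(2 * (n - nrow(out)), 16)
    px <- runif(m, bb[1], bb[2]); py <- runif(m, bb[3], bb[4])
    keep <- point_in_poly(px, py, poly)
    out <- rbind(out, cbind(px[keep], py[keep]))
    tries <- tries + 1
  }
  if (nrow(out) < n) stop_oro("failed to sample points inside polygon")
  out[seq_len(n), , drop = FALSE]
}

#' Generate a complete synthetic world
#'
#' Deterministic for a fixed config (all randomness flows from named
#' sub-streams of `config$seed`). See [world_config] for the knobs.
#'
#' @param config a [world_config].
#' @param alien_fraction,records_per_species forwarded to
#'   [simulate_occurrences].
#' @return an object of class `synth_world`: realms, mountains (with
#'   hierarchy, area, elevation limits), `dem`, predictor rasters, a monthly
#'   climate stack, cities/ports, species ranges, occurrence records,
#'   protected areas, and a `truth` list (per-record alien flags, true
#'   mountain geometry classes, true realm flows, per-mountain alien richness,
#'   and the generative GLMM parameters).
#' @export
generate_world <- function(config = world_config(), alien_fraction = 0.3,
                           records_per_species = 30) {
  if (!inherits(config, "world_config")) stop_oro("config must be a world_config")
  ext <- config$grid_extent
  res <- config$raster_resolution

  ## --- realms: Voronoi tiles of seed points --------------------------------
  set.seed(substream_seed(config$seed, "realms"))
  k <- config$n_realms
  if (k == 1) {
    realm_geoms <- list(R01 = cbind(c(ext[1], ext[2], ext[2], ext[1]),
                                    c(ext[3], ext[3], ext[4], ext[4])))
    seeds_x <- mean(ext[1:2]); seeds_y <- mean(ext[3:4])
  } else {
    # jittered grid of seeds keeps tiles comparable in size
    gx <- ceiling(sqrt(k))
    gy <- ceiling(k / gx)
    cand <- expand.grid(
      x = ext[1] + (seq_len(gx) - 0.5) * (ext[2] - ext[1]) / gx,
      y = ext[3] + (seq_len(gy) - 0.5) * (ext[4] - ext[3]) / gy)
    cand <- cand[seq_len(k), ]
    seeds_x <- cand$x + runif(k, -0.15, 0.15) * (ext[2] - ext[1]) / gx
    seeds_y <- cand$y + runif(k, -0.15, 0.15) * (ext[4] - ext[3]) / gy
    dd <- deldir::deldir(seeds_x, seeds_y, rw = ext[c(1, 2, 3, 4)])
    tiles <- deldir::tile.list(dd)
    realm_geoms <- lapply(tiles, function(t) cbind(t$x, t$y))
    names(realm_geoms) <- sprintf("R%02d", seq_len(k))
  }
  n_cont <- min(3L, k)
  cont_of_realm <- if (n_cont == 1) rep("C1", k) else
    sprintf("C%d", as.integer(cut(rank(seeds_x, ties.method = "first"),
                                  n_cont, labels = FALSE)))
  realms <- ovd_layer(realm_geoms,
                      data.frame(realm_id = names(realm_geoms),
                                 continent_id = cont_of_realm,
                                 stringsAsFactors = FALSE))

  ## --- mountains: disjoint convex polygons ---------------------------------
  set.seed(substream_seed(config$seed, "mountains"))
  nm <- config$n_mountains
  r_lo <- max(1.15, 3 * res)  # >= ~45 cells under the center rule
  r_hi <- max(r_lo + 0.2, min(1.5, 0.06 * (ext[2] - ext[1])))
  centers <- matrix(NA_real_, nm, 2)
  radii <- numeric(nm)
  placed <- 0; tries <- 0
  while (placed < nm && tries < 50000) {
    tries <- tries + 1
    r <- runif(1, r_lo, r_hi)
    cx <- runif(1, ext[1] + r, ext[2] - r)
    cy <- runif(1, ext[3] + r, ext[4] - r)
    ok <- placed == 0 ||
      all(sqrt((centers[seq_len(placed), 1] - cx)^2 +
               (centers[seq_len(placed), 2] - cy)^2) >
          radii[seq_len(placed)] + r + 0.15)
    if (ok) {
      placed <- placed + 1
      centers[placed, ] <- c(cx, cy); radii[placed] <- r
    }
  }
  if (placed < nm)
    stop_oro("configuration error: could not place ", nm,
             " disjoint mountains in the extent; reduce n_mountains")
  mt_ids <- sprintf("M%03d", seq_len(nm))
  mt_geoms <- lapply(seq_len(nm), function(i)
    random_convex_polygon(centers[i, ], radii[i], k = 14))
  names(mt_geoms) <- mt_ids

  # hierarchy: continent from the containing realm, then k-means splits
  realm_of_mt <- locate_points(centers[, 1], centers[, 2], realms)
  cont_map <- setNames(realms$data$continent_id, realms$data$realm_id)
  cont_of_mt <- unname(cont_map[realm_of_mt])
  region_of_mt <- rep(NA_character_, nm)
  system_of_mt <- rep(NA_character_, nm)
  for (cc in unique(cont_of_mt)) {
    i_c <- which(cont_of_mt == cc)
    kr <- max(1L, min(3L, length(i_c) %/% 8L))
    reg <- if (kr == 1 || length(i_c) < 4) rep(1L, length(i_c)) else
      kmeans(centers[i_c, , drop = FALSE], kr, nstart = 3)$cluster
    region_of_mt[i_c] <- sprintf("%s_G%d", cc, reg)
    for (rr in unique(region_of_mt[i_c])) {
      i_r <- which(region_of_mt == rr)
      ks <- max(1L, min(3L, length(i_r) %/% 4L))
      sys <- if (ks == 1 || length(i_r) < 4) rep(1L, length(i_r)) else
        kmeans(centers[i_r, , drop = FALSE], ks, nstart = 3)$cluster
      system_of_mt[i_r] <- sprintf("%s_S%d", rr, sys)
    }
  }

  ## --- true geometry classes and the DEM -----------------------------------
  set.seed(substream_seed(config$seed, "geometry"))
  true_geometry <- sample(GEOMETRY_CLASSES, nm, replace = TRUE,
                          prob = c(0.35, 0.15, 0.35, 0.15))
  nx <- round((ext[2] - ext[1]) / res)
  ny <- round((ext[4] - ext[3]) / res)
  dem_r <- ovd_raster(matrix(0, ny, nx), ext)
  cc <- raster_centers(dem_r)

  set.seed(substream_seed(config$seed, "dem"))
  base <- 120 + 40 * smooth_field(cc$x, cc$y)
  base[base < 1] <- 1
  dem_vals <- base
  elev_min <- numeric(nm); elev_max <- numeric(nm)
  mt_cells <- vector("list", nm)
  for (i in seq_len(nm)) {
    idx <- cells_in_polygon(dem_r, mt_geoms[[i]])
    mt_cells[[i]] <- idx
    relief <- runif(1, 1200, 3200)
    q <- draw_class_elevations(true_geometry[i], nrow(idx))
    dem_vals[idx] <- base[idx] + relief * q
    elev_min[i] <- min(dem_vals[idx]); elev_max[i] <- max(dem_vals[idx])
  }
  dem <- ovd_raster(dem_vals, ext)

  mountains <- ovd_layer(mt_geoms, data.frame(
    mountain_id = mt_ids,
    system_id = system_of_mt, region_id = region_of_mt,
    continent_id = cont_of_mt,
    area_km2 = vapply(mt_geoms, polygon_area_km2, 0),
    elev_min = elev_min, elev_max = elev_max,
    stringsAsFactors = FALSE))

  ## --- anthropogenic predictor rasters -------------------------------------
  set.seed(substream_seed(config$seed, "fields"))
  mid_y <- mean(ext[3:4]); span_y <- ext[4] - ext[3]
  lat_trend <- outer(cc$y, cc$x, function(y, x) (y - mid_y) / span_y)
  predictors <- list(
    pop_density = ovd_raster(exp(3.5 + 1.1 * smooth_field(cc$x, cc$y)), ext),
    road_density = ovd_raster(exp(3.0 + 0.9 * smooth_field(cc$x, cc$y)), ext),
    bii = ovd_raster(stats::plogis(1.2 + 1.5 * smooth_field(cc$x, cc$y)), ext),
    # sampling completeness biased towards the "north", like the real layer
    completeness = ovd_raster(
      stats::plogis(0.4 + 1.2 * smooth_field(cc$x, cc$y) + 2.5 * lat_trend),
      ext))

  ## --- climate: monthly minimum temperature --------------------------------
  climate <- simulate_climate_series(
    trend = 0.02, spatial_gradient = 0.01, noise_sd = 0.3, years = 30,
    seed = substream_seed(config$seed, "climate"), extent = ext,
    res = config$climate_resolution)

  ## --- cities and ports ----------------------------------------------------
  set.seed(substream_seed(config$seed, "gravity"))
  cities <- data.frame(city_id = sprintf("city%02d", 1:25),
                       lon = runif(25, ext[1], ext[2]),
                       lat = runif(25, ext[3], ext[4]))
  side <- sample(4, 12, replace = TRUE)
  tpos <- runif(12)
  ports <- data.frame(
    port_id = sprintf("port%02d", 1:12),
    lon = ifelse(side == 1, ext[1], ifelse(side == 2, ext[2],
                 ext[1] + tpos * (ext[2] - ext[1]))),
    lat = ifelse(side == 3, ext[3], ifelse(side == 4, ext[4],
                 ext[3] + tpos * (ext[4] - ext[3]))))

  ## --- species pool with convex native ranges ------------------------------
  set.seed(substream_seed(config$seed, "species"))
  ns <- config$n_species_pool
  sp_class <- sample(TAXON_CLASSES, ns, replace = TRUE,
                     prob = config$taxon_class_weights)
  ext_ring <- cbind(c(ext[1], ext[2], ext[2], ext[1]),
                    c(ext[3], ext[3], ext[4], ext[4]))
  species <- vector("list", ns)
  for (i in seq_len(ns)) {
    ctr <- c(runif(1, ext[1] + 1, ext[2] - 1), runif(1, ext[3] + 1, ext[4] - 1))
    rr <- runif(1, 1.5, 4.5)
    rng <- clip_polygon_convex(random_convex_polygon(ctr, rr, 10), ext_ring)
    nr <- names(realm_geoms)[vapply(realm_geoms, function(g)
      intersection_area_km2(rng, g) > 1e-6, TRUE)]
    species[[i]] <- list(species_id = sprintf("sp%04d", i),
                         taxon_class = sp_class[i],
                         native_polygons = list(rng),
                         native_realms = nr)
  }
  names(species) <- vapply(species, `[[`, "", "species_id")

  ## --- protected areas -----------------------------------------------------
  set.seed(substream_seed(config$seed, "pas"))
  npa <- max(3L, round(0.5 * nm))
  host <- sample(nm, npa, replace = TRUE)
  pa_geoms <- vector("list", npa)
  for (i in seq_len(npa)) {
    h <- host[i]
    ctr <- centers[h, ] + runif(2, -0.35, 0.35) * radii[h]
    pa_geoms[[i]] <- random_convex_polygon(ctr, runif(1, 0.3, 0.65) * radii[h], 10)
  }
  names(pa_geoms) <- sprintf("PA%03d", seq_len(npa))
  pas <- ovd_layer(pa_geoms, data.frame(
    pa_id = names(pa_geoms),
    status = sample(c("Designated", "Inscribed", "Established", "Proposed",
                      "Adopted"), npa, replace = TRUE,
                    prob = c(0.6, 0.05, 0.1, 0.15, 0.1)),
    iucn_category = sample(c("Ia", "Ib", "II", "III", "IV", "V", "VI",
                             "Not Reported"), npa, replace = TRUE,
                           prob = c(0.05, 0.05, 0.2, 0.1, 0.2, 0.2, 0.1, 0.1)),
    stringsAsFactors = FALSE))

  world <- structure(list(
    config = config, realms = realms, mountains = mountains, dem = dem,
    predictors = predictors, climate = climate, cities = cities,
    ports = ports, species = species, pas = pas,
    truth = list(geometry = setNames(true_geometry, mt_ids),
                 glmm = list(
                   beta = c("(Intercept)" = -5.0, pop_density = 0.06,
                            road_density = 0.16, dist_cities = -0.07,
                            dist_ports = -0.19, bii = -0.12,
                            gvocc_tmin = 0.06, roughness = 0.35,
                            elev_range = -0.62, completeness = 0.56,
                            geometry_pyramid = 0.17,
                            geometry_inverse_pyramid = -0.1,
                            geometry_hourglass = 0.05),
                   theta = 2, sigma = c(continent = 0.1, region = 0.2,
                                        system = 0.4)))),
    class = "synth_world")

  ## --- occurrence records with truth flags ---------------------------------
  occ <- simulate_occurrences(world, alien_fraction = alien_fraction,
                              records_per_species = records_per_species,
                              seed = substream_seed(config$seed, "occurrences"))
  world$occurrences <- occ$records
  world$truth$records <- occ$truth
  world$truth$flow <- occ$truth_flow
  world$truth$richness <- occ$truth_richness
  world
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf(
    "<synth_world: %d realms, %d mountains, %d species, %d records, %d PAs>\n",
    nrow(x$realms$data), nrow(x$mountains$data), length(x$species),
    nrow(x$occurrences %||% data.frame()), nrow(x$pas$data)))
  invisible(x)
}

#' Simulate occurrence records over a synthetic world
#'
#' Each species receives a Poisson number of records; a binomial share of them
#' is truth-alien (a point inside some mountain but outside all of the
#' species' native polygons), the rest truth-native (inside a native
#' polygon). Species whose native range leaves no mountain room for alien
#' points are warned about and receive native records only.
#'
#' @param world a `synth_world`.
#' @param alien_fraction probability a record is alien (in `[0, 1]`).
#' @param records_per_species Poisson mean records per species.
#' @param seed integer seed.
#' @return list with `records` (record_id, species_id, taxon_class, lon,
#'   lat), `truth` (adds true_alien, mountain_id, realm_id), `truth_flow`
#'   (donor x recipient species counts) and `truth_richness` (per mountain x
#'   class distinct alien species).
#' @export
simulate_occurrences <- function(world, alien_fraction = 0.3,
                                 records_per_species = 30, seed = 1L) {
  stopifnot(inherits(world, "synth_world"))
  if (alien_fraction < 0 || alien_fraction > 1)
    stop_oro("alien_fraction must be in [0, 1]")
  set.seed(seed)
  mt_ids <- layer_ids(world$mountains)
  rows <- vector("list", length(world$species))
  skipped <- character(0)
  for (si in seq_along(world$species)) {
    sp <- world$species[[si]]
    n_i <- rpois(1, records_per_species)
    if (n_i == 0) next
    n_alien <- stats::rbinom(1, n_i, alien_fraction)
    pts <- matrix(numeric(0), 0, 2); alien_flag <- logical(0)
    mt_of <- character(0)
    if (n_i - n_alien > 0) {
      nat <- sample_point_in_polygon(sp$native_polygons[[
        sample.int(length(sp$native_polygons), 1)]], n_i - n_alien)
      pts <- rbind(pts, nat)
      alien_flag <- c(alien_flag, rep(FALSE, nrow(nat)))
      mt_of <- c(mt_of, rep(NA_character_, nrow(nat)))
    }
    placed_alien <- 0; guard <- 0
    while (placed_alien < n_alien && guard < 60 * n_alien + 60) {
      guard <- guard + 1
      m <- sample(mt_ids, 1)
      cand <- sample_point_in_polygon(world$mountains$geoms[[m]], 4)
      in_native <- rep(FALSE, nrow(cand))
      for (np in sp$native_polygons)
        in_native <- in_native | point_in_poly(cand[, 1], cand[, 2], np)
      ok <- which(!in_native)
      if (length(ok)) {
        take <- ok[seq_len(min(length(ok), n_alien - placed_alien))]
        pts <- rbind(pts, cand[take, , drop = FALSE])
        alien_flag <- c(alien_flag, rep(TRUE, length(take)))
        mt_of <- c(mt_of, rep(m, length(take)))
        placed_alien <- placed_alien + length(take)
      }
    }
    if (placed_alien < n_alien) skipped <- c(skipped, sp$species_id)
    rows[[si]] <- data.frame(
      species_id = sp$species_id, taxon_class = sp$taxon_class,
      lon = pts[, 1], lat = pts[, 2], true_alien = alien_flag,
      mountain_id = mt_of, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warn_oro(length(skipped), " species could not receive all their alien ",
             "records (native range covers the candidate mountains); ",
             "records skipped")
  df <- do.call(rbind, rows)
  df <- df[sample.int(nrow(df)), ]  # shuffle so record order carries no signal
  df$record_id <- sprintf("rec%06d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df$realm_id <- locate_points(df$lon, df$lat, world$realms)
  # native records may or may not fall inside mountains; annotate for truth
  nat <- which(!df$true_alien)
  df$mountain_id[nat] <- locate_points(df$lon[nat], df$lat[nat],
                                       world$mountains)

  records <- df[c("record_id", "species_id", "taxon_class", "lon", "lat")]
  truth <- df[c("record_id", "species_id", "taxon_class", "lon", "lat",
                "true_alien", "mountain_id", "realm_id")]

  # true realm flows: species' native realms -> realms of its alien records
  realm_ids <- layer_ids(world$realms)
  fl <- matrix(0L, length(realm_ids), length(realm_ids),
               dimnames = list(donor = realm_ids, recipient = realm_ids))
  al <- truth[truth$true_alien & !is.na(truth$realm_id), ]
  for (sid in unique(al$species_id)) {
    rec <- unique(al$realm_id[al$species_id == sid])
    don <- world$species[[sid]]$native_realms
    fl[don, rec] <- fl[don, rec] + 1L
  }
  # true per-mountain alien richness by class
  alm <- al[!is.na(al$mountain_id), ]
  rich <- if (nrow(alm)) {
    u <- unique(alm[c("mountain_id", "taxon_class", "species_id")])
    aggregate(species_id ~ mountain_id + taxon_class, u, length)
  } else data.frame(mountain_id = character(0), taxon_class = character(0),
                    species_id = integer(0))
  names(rich)[3] <- "n_species"

  list(records = records, truth = truth, truth_flow = fl,
       truth_richness = rich)
}

#' Simulate per-mountain alien richness counts from a NB mixed model
#'
#' Counts are drawn from a negative binomial (NB2) with
#' `mu = exp(log(area) + X beta + u_continent + u_region + u_system)` and
#' dispersion `theta`; the random intercepts are Gaussian with the given SDs.
#'
#' @param design data.frame with one row per mountain: the predictor columns
#'   named in `beta`, an `area_km2` column, and `continent_id`, `region_id`,
#'   `system_id` grouping columns.
#' @param beta named coefficient vector; may include `"(Intercept)"` and
#'   geometry dummy terms (`geometry_pyramid` etc. when `design$geometry`
#'   exists).
#' @param theta NB dispersion (> 0).
#' @param sigma named SDs `c(continent=, region=, system=)`, all >= 0.
#' @param seed integer seed.
#' @return `design` with added columns `mu` and `n_species`.
#' @export
simulate_richness_counts <- function(design, beta, theta, sigma, seed = 1L) {
  stopifnot(is.data.frame(design), theta > 0, all(sigma >= 0))
  sigma <- sigma[c("continent", "region", "system")]
  if (any(is.na(sigma))) stop_oro("sigma must name continent, region, system")
  set.seed(seed)
  b0 <- if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0
  eta <- rep(b0, nrow(design))
  terms <- setdiff(names(beta), "(Intercept)")
  for (tm in terms) {
    if (tm %in% names(design)) {
      v <- design[[tm]]
      if (any(is.na(v))) stop_oro("missing values in predictor ", tm)
      eta <- eta + beta[[tm]] * v
    } else if (startsWith(tm, "geometry_")) {
      lev <- sub("^geometry_", "", tm)
      eta <- eta + beta[[tm]] * as.numeric(design$geometry == lev)
    } else stop_oro("coefficient ", tm, " matches no design column")
  }
  eta <- eta + log(design$area_km2)
  for (lev in c("continent", "region", "system")) {
    g <- factor(design[[paste0(lev, "_id")]])
    u <- rnorm(nlevels(g), 0, sigma[[lev]])
    eta <- eta + u[as.integer(g)]
  }
  if (any(!is.finite(eta)))
    stop_oro("non-finite linear predictor at row(s): ",
             paste(head(which(!is.finite(eta)), 5), collapse = ", "))
  design$mu <- exp(eta)
  design$n_species <- MASS::rnegbin(nrow(design), mu = design$mu,
                                    theta = theta)
  design
}

#' Simulate a monthly minimum-temperature raster stack
#'
#' Cell values follow `base + gradient * d_north + trend * t + noise`, where
#' `d_north` is the great-circle distance (km) north of the southern extent
#' edge and `t` is time in years (months at mid-month). A purely meridional
#' gradient makes the construction exactly consistent with the
#' latitude-corrected gradient estimator in [gvocc].
#'
#' @param trend warming trend in degrees C per year.
#' @param spatial_gradient meridional gradient in degrees C per km.
#' @param noise_sd iid Gaussian noise SD in degrees C.
#' @param years number of simulated years (>= 2).
#' @param seed integer seed.
#' @param extent numeric length 4 (xmin, xmax, ymin, ymax).
#' @param res cell size in degrees.
#' @param base_temp intercept in degrees C at the southern edge.
#' @param start_year calendar year of the first layer.
#' @return an [ovd_stack] with `years * 12` monthly layers.
#' @export
simulate_climate_series <- function(trend = 0.02, spatial_gradient = 0.01,
                                    noise_sd = 0.3, years = 30, seed = 1L,
                                    extent = c(0, 40, 5, 45), res = 0.25,
                                    base_temp = 12, start_year = 1990L) {
  if (years < 2) stop_oro("climate series needs years >= 2")
  set.seed(seed)
  nx <- round((extent[2] - extent[1]) / res)
  ny <- round((extent[4] - extent[3]) / res)
  yc <- extent[4] - (seq_len(ny) - 0.5) * res   # north to south
  d_north <- (yc - extent[3]) * KM_PER_DEG
  spatial <- matrix(base_temp + spatial_gradient * d_north, ny, nx)
  nl <- years * 12
  arr <- array(NA_real_, c(ny, nx, nl))
  year <- rep(seq_len(years), each = 12)
  month <- rep(1:12, years)
  t_yr <- (year - 1) + (month - 0.5) / 12
  for (l in seq_len(nl)) {
    layer <- spatial + trend * t_yr[l]
    if (noise_sd > 0) layer <- layer + rnorm(length(layer), 0, noise_sd)
    arr[, , l] <- layer
  }
  ovd_stack(arr, start_year - 1 + year, month, extent)
}

#' Write every layer of a synthetic world to a directory
#'
#' GeoJSON for polygon and point layers, Darwin-Core-style CSV for
#' occurrences, ESRI ASCII grids for rasters, long CSV for the climate
#' stack, and JSON for the ground truth.
#'
#' @param world a `synth_world`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_geojson_polygons(world$realms, file.path(dir, "realms.geojson"))
  write_geojson_polygons(world$mountains, file.path(dir, "mountains.geojson"))
  write_geojson_polygons(world$pas, file.path(dir, "protected_areas.geojson"))
  write_geojson_points(world$cities, file.path(dir, "cities.geojson"))
  write_geojson_points(world$ports, file.path(dir, "ports.geojson"))
  write_ranges_geojson(world$species, file.path(dir, "native_ranges.geojson"))
  write_occurrences_csv(world$occurrences, file.path(dir, "occurrences.csv"))
  write_asc(world$dem, file.path(dir, "dem.asc"))
  for (nm in names(world$predictors))
    write_asc(world$predictors[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_stack_csv(world$climate, file.path(dir, "climate_tmin.csv"))
  truth <- world$truth
  truth$flow <- list(realms = rownames(truth$flow),
                     counts = unname(apply(truth$flow, 1, as.list)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
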