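# Mountain-level predictors: terrain roughness, elevation-distribution
# geometry classes, gradient-based climate velocity, zonal statistics of the
# anthropogenic layers, and nearest-distance metrics.

#' Terrain roughness raster
#'
#' Each cell becomes the difference between the maximum and the minimum
#' elevation over the cell and its eight neighbours; edge cells use the
#' neighbours that exist; `NA` cells stay `NA`.
#'
#' @param dem an [ovd_raster] with at least 3 x 3 valid cells.
#' @return an [ovd_raster] of roughness values (same units as the DEM).
#' @export
terrain_roughness <- function(dem) {
  v <- dem$values
  if (sum(!is.na(v)) < 9) stop_oro("DEM has fewer than 9 valid cells")
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop_oro("DEM must be at least 3 x 3")
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- v
  mx <- matrix(-Inf, nr, nc); mn <- matrix(Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    sh <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    mx <- pmax(mx, sh, na.rm = TRUE)
    mn <- pmin(mn, sh, na.rm = TRUE)
  }
  out <- mx - mn
  out[is.na(v)] <- NA  # nodata propagates at the focal cell
  ovd_raster(out, c(dem$xmin, dem$xmax, dem$ymin, dem$ymax))
}

#' Classify a mountain's geometry from its elevation distribution
#'
#' Rule order: (1) hourglass when the dip statistic exceeds `dip_threshold`
#' AND the dip test rejects unimodality at `p_threshold`, irrespective of
#' skewness; otherwise (2) pyramid when the moment skewness is >= `skew_threshold`;
#' (3) inverse pyramid when it is <= `-skew_threshold`; (4) diamond otherwise.
#'
#' @param elev numeric vector of cell elevations for one mountain.
#' @param min_cells minimum sample size accepted.
#' @param dip_threshold dip statistic threshold for the hourglass rule.
#' @param p_threshold significance level of the dip test.
#' @param skew_threshold absolute skewness separating pyramid / inverse
#'   pyramid from diamond.
#' @param n_mc optional Monte-Carlo replicates for the dip p-value (default:
#'   interpolate the shipped 50,000-replicate null table).
#' @return list: `n`, `skewness`, `dip`, `p_dip`, `class`.
#' @export
classify_geometry <- function(elev, min_cells = 30, dip_threshold = 0.01,
                              p_threshold = 0.05, skew_threshold = 0.5,
                              n_mc = NULL) {
  elev <- elev[!is.na(elev)]
  n <- length(elev)
  if (n < min_cells)
    stop_oro("classification refused: ", n, " cells < minimum of ", min_cells)
  m2 <- mean((elev - mean(elev))^2)
  g1 <- mean((elev - mean(elev))^3) / m2^1.5  # moment coefficient of skewness
  d <- dip_stat(elev)
  p <- dip_pvalue(d, n, n_mc = n_mc)
  cls <- if (d > dip_threshold && p < p_threshold) "hourglass"
         else if (g1 >= skew_threshold) "pyramid"
         else if (g1 <= -skew_threshold) "inverse_pyramid"
         else "diamond"
  list(n = n, skewness = g1, dip = d, p_dip = p, class = cls)
}

#' Gradient-based velocity of climate change (gVoCC)
#'
#' Per cell, the temporal trend `b` is the OLS slope of annual mean
#' temperature against year (degrees C per year); the spatial gradient `g` is
#' the magnitude of the gradient of the time-mean field from central (edge:
#' one-sided) differences with latitude-corrected cell widths (degrees C per
#' km); the velocity is `v = b / g` (km per year, signed by the trend).
#' Cells with `g < eps` are flagged undefined (`NA`), not infinite.
#'
#' @param climate an [ovd_stack] spanning >= 10 years of monthly layers.
#' @param eps minimum gradient magnitude considered defined (degrees C/km).
#' @return list of [ovd_raster]s: `trend`, `gradient`, `velocity`.
#' @export
gvocc <- function(climate, eps = 1e-6) {
  stopifnot(inherits(climate, "ovd_stack"))
  years <- sort(unique(climate$year))
  if (length(years) < 10) stop_oro("climate stack must span >= 10 years")
  nr <- dim(climate$values)[1]; nc <- dim(climate$values)[2]
  ext <- c(climate$xmin, climate$xmax, climate$ymin, climate$ymax)

  # annual means, then the closed-form OLS slope against year
  ann <- array(0, c(nr, nc, length(years)))
  for (k in seq_along(years)) {
    sel <- which(climate$year == years[k])
    ann[, , k] <- apply(climate$values[, , sel, drop = FALSE], c(1, 2), mean)
  }
  ty <- years - mean(years)
  denom <- sum(ty^2)
  b <- matrix(0, nr, nc)
  for (k in seq_along(years)) b <- b + ty[k] * ann[, , k]
  b <- b / denom

  # spatial gradient of the time-mean field
  tm <- apply(ann, c(1, 2), mean)
  lat <- raster_centers(stack_band(climate, 1))$y
  dx_km <- climate$res * KM_PER_DEG * cos(lat * pi / 180)  # per row
  dy_km <- climate$res * KM_PER_DEG
  gx <- matrix(NA_real_, nr, nc); gy <- matrix(NA_real_, nr, nc)
  if (nc >= 2) {
    if (nc >= 3)
      gx[, 2:(nc - 1)] <- (tm[, 3:nc, drop = FALSE] -
                           tm[, 1:(nc - 2), drop = FALSE]) / (2 * dx_km)
    gx[, 1] <- (tm[, 2] - tm[, 1]) / dx_km
    gx[, nc] <- (tm[, nc] - tm[, nc - 1]) / dx_km
  } else gx[] <- 0
  if (nr >= 2) {
    # row 1 is north: value decreases southwards along rows
    if (nr >= 3)
      gy[2:(nr - 1), ] <- (tm[1:(nr - 2), , drop = FALSE] -
                           tm[3:nr, , drop = FALSE]) / (2 * dy_km)
    gy[1, ] <- (tm[1, ] - tm[2, ]) / dy_km
    gy[nr, ] <- (tm[nr - 1, ] - tm[nr, ]) / dy_km
  } else gy[] <- 0
  g <- sqrt(gx^2 + gy^2)
  v <- ifelse(g >= eps, b / g, NA_real_)

  list(trend = ovd_raster(b, ext), gradient = ovd_raster(g, ext),
       velocity = ovd_raster(v, ext))
}

#' Mountain-level predictor table
#'
#' Computes, per mountain, all modelled predictors: zonal means (cells whose
#' center falls in the polygon) of population density, road density,
#' biodiversity intactness, sampling completeness, terrain roughness and
#' climate velocity; minimum great-circle distances to cities and ports;
#' elevation range from the inventory attributes; and the geometry class of
#' the within-mountain elevation distribution.
#'
#' @param mountains [ovd_layer] with `area_km2`, `elev_min`, `elev_max`.
#' @param rasters named list of [ovd_raster]s: `pop_density`, `road_density`,
#'   `bii`, `completeness`.
#' @param dem elevation [ovd_raster] (drives roughness and geometry).
#' @param velocity the `velocity` raster from [gvocc].
#' @param cities,ports data.frames with `lon`, `lat`.
#' @param min_defined_frac mountains with a smaller fraction of defined
#'   velocity cells are flagged in `gvocc_flagged`.
#' @param geometry_args list of arguments forwarded to [classify_geometry]
#'   (thresholds etc.).
#' @return data.frame keyed by `mountain_id` with the ten predictors, the
#'   area, hierarchy columns, and diagnostic columns; geometry diagnostics
#'   (`skewness`, `dip`, `p_dip`) ride along.
#' @export
extract_predictors <- function(mountains, rasters, dem, velocity,
                               cities, ports, min_defined_frac = 0.25,
                               geometry_args = list()) {
  ids <- layer_ids(mountains)
  md <- mountains$data
  rough <- terrain_roughness(dem)
  zon <- function(r) zonal_mean(r, mountains)$mean
  out <- data.frame(
    mountain_id = ids,
    system_id = md$system_id, region_id = md$region_id,
    continent_id = md$continent_id, area_km2 = md$area_km2,
    pop_density = zon(rasters$pop_density),
    road_density = zon(rasters$road_density),
    bii = zon(rasters$bii),
    completeness = zon(rasters$completeness),
    roughness = zon(rough),
    elev_range = md$elev_max - md$elev_min,
    stringsAsFactors = FALSE)

  vz <- zonal_mean(velocity, mountains)      # NA cells (undefined v) dropped
  tot <- zonal_mean(ovd_raster(velocity$values * 0 + 1,
                               c(velocity$xmin, velocity$xmax,
                                 velocity$ymin, velocity$ymax)), mountains)
  out$gvocc_tmin <- vz$mean
  out$gvocc_flagged <- vz$n_cells < min_defined_frac * pmax(1, tot$n_cells)

  out$dist_cities <- NA_real_; out$dist_ports <- NA_real_
  out$geometry <- NA_character_
  out$skewness <- NA_real_; out$dip <- NA_real_; out$p_dip <- NA_real_
  for (i in seq_along(ids)) {
    g <- mountains$geoms[[ids[i]]]
    out$dist_cities[i] <- min(dist_poly_points_km(g, cities$lon, cities$lat))
    out$dist_ports[i] <- min(dist_poly_points_km(g, ports$lon, ports$lat))
    idx <- cells_in_polygon(dem, g)
    cls <- try(do.call(classify_geometry,
                       c(list(dem$values[idx]), geometry_args)),
               silent = TRUE)
    if (!inherits(cls, "try-error")) {
      out$geometry[i] <- cls$class
      out$skewness[i] <- cls$skewness
      out$dip[i] <- cls$dip
      out$p_dip[i] <- cls$p_dip
    }
  }
  miss <- colSums(is.na(out[c("pop_density", "road_density", "bii",
                              "completeness", "roughness", "gvocc_tmin",
                              "geometry")]))
  attr(out, "metadata") <- list(
    zonal_rule = "cell center inside polygon",
    distance = "great-circle, polygon boundary/interior minimum",
    gvocc_aggregation = "annual means before trend fitting",
    skewness = "moment coefficient (no small-sample correction)",
    missing_by_column = as.list(miss))
  out
}
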