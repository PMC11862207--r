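# Independent brute-force oracles and shared fixtures.
#
# The oracles are deliberately written from scratch (plain ray casting,
# exhaustive loops) so they share no code with the production paths they
# check.

# even-odd ray casting with an explicit boundary check; one point at a time
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  on_edge <- FALSE
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary: point collinear with and between the edge endpoints
    if (abs((px - xi) * (yj - yi) - (py - yi) * (xj - xi)) < 1e-12 &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12)
      on_edge <- TRUE
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside || on_edge
}

# exhaustive point-to-layer assignment (lexicographically smallest id wins)
assign_oracle <- function(x, y, layer) {
  ids <- sort(names(layer$geoms))
  out <- rep(NA_character_, length(x))
  for (k in seq_along(x)) {
    for (id in ids) {
      if (pip_oracle(x[k], y[k], layer$geoms[[id]])) { out[k] <- id; break }
    }
  }
  out
}

# exhaustive zonal mean: loop every cell center
zonal_oracle <- function(r, poly) {
  cc <- raster_centers(r)
  vals <- c()
  for (i in seq_along(cc$y)) for (j in seq_along(cc$x)) {
    if (pip_oracle(cc$x[j], cc$y[i], poly)) vals <- c(vals, r$values[i, j])
  }
  if (!length(vals)) NA_real_ else mean(vals, na.rm = TRUE)
}

# exhaustive 3x3 window roughness
roughness_oracle <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    w <- v[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    out[i, j] <- max(w, na.rm = TRUE) - min(w, na.rm = TRUE)
  }
  out
}

# small shared synthetic world, generated once per test run
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(generate_world(
        world_config(n_mountains = 40, n_species_pool = 200, seed = 42)))
    cache
  }
})

# a unit square polygon at (x0, y0)
square <- function(x0, y0, w = 1)
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w))

# tiny two-mountain layer with known areas
two_mountains <- function() {
  ovd_layer(list(M1 = square(0, 0, 2), M2 = square(5, 0, 2)),
            data.frame(mountain_id = c("M1", "M2"),
                       system_id = c("S1", "S2"),
                       region_id = c("G1", "G1"),
                       continent_id = c("C1", "C1"),
                       area_km2 = c(100, 100),
                       elev_min = c(0, 0), elev_max = c(1000, 1500)))
}

make_records <- function(lon, lat, species = "sp0001", class = "bird") {
  n <- length(lon)
  data.frame(record_id = sprintf("r%03d", seq_len(n)),
             species_id = rep_len(species, n),
             taxon_class = rep_len(class, n),
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}
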