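# Planar/geodesic geometry helpers for lon/lat polygon layers.
#
# Polygons are plain two-column matrices (lon, lat) holding one open ring
# (no repeated closing vertex).  A polygon layer couples a named list of such
# rings with an attribute table; this is deliberately minimal -- containment
# tests are done in lon/lat, areas on an equal-area projection.

#' Construct a polygon layer
#'
#' @param geoms named list of two-column (lon, lat) matrices, one open ring
#'   per feature. Names are the feature ids.
#' @param data data.frame of attributes, one row per feature; must contain an
#'   id column whose values equal `names(geoms)` in order.
#' @param id_col name of the id column in `data`.
#' @return an object of class `ovd_layer`.
#' @export
ovd_layer <- function(geoms, data, id_col = names(data)[1]) {
  stopifnot(is.list(geoms), is.data.frame(data), nrow(data) == length(geoms))
  if (is.null(names(geoms)) || any(names(geoms) == ""))
    stop_oro("all geometries must be named")
  if (!identical(as.character(data[[id_col]]), names(geoms)))
    stop_oro("layer ids in `data` must match names(geoms) in order")
  for (g in geoms) {
    if (!is.matrix(g) || ncol(g) != 2 || nrow(g) < 3)
      stop_oro("each geometry must be a 2-column matrix with >= 3 vertices")
  }
  structure(list(geoms = geoms, data = data, id_col = id_col),
            class = "ovd_layer")
}

#' @export
print.ovd_layer <- function(x, ...) {
  cat(sprintf("<ovd_layer: %d polygons, %d attribute columns>\n",
              length(x$geoms), ncol(x$data)))
  print(head(x$data, 4))
  invisible(x)
}

layer_ids <- function(layer) as.character(layer$data[[layer$id_col]])

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param x,y point coordinates (vectors of equal length).
#' @param poly two-column matrix, one open ring.
#' @return logical vector.
#' @export
point_in_poly <- function(x, y, poly) {
  sp::point.in.polygon(x, y, poly[, 1], poly[, 2]) > 0
}

#' Locate points in a set of disjoint polygons
#'
#' Each point is assigned the id of the polygon containing it (boundary
#' inclusive). Points on a shared border are assigned deterministically to the
#' lexicographically smallest id; points in no polygon get `NA`.
#'
#' @param x,y point coordinates.
#' @param layer an [ovd_layer].
#' @return character vector of ids (or `NA`).
#' @export
locate_points <- function(x, y, layer) {
  ids <- layer_ids(layer)
  out <- rep(NA_character_, length(x))
  for (id in sort(ids)) {
    g <- layer$geoms[[id]]
    todo <- which(is.na(out) &
                  x >= min(g[, 1]) & x <= max(g[, 1]) &
                  y >= min(g[, 2]) & y <= max(g[, 2]))
    if (!length(todo)) next
    inside <- point_in_poly(x[todo], y[todo], g)
    out[todo[inside]] <- id
  }
  out
}

# signed area in the coordinate units of the ring (positive = counterclockwise)
ring_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# sinusoidal (equal-area) projection of lon/lat degrees to km
project_sinusoidal <- function(p) {
  cbind(p[, 1] * KM_PER_DEG * cos(p[, 2] * pi / 180),
        p[, 2] * KM_PER_DEG)
}

#' Polygon area in square kilometres (equal-area projection)
#'
#' @param poly two-column (lon, lat) matrix, one open ring.
#' @return area in km^2.
#' @export
polygon_area_km2 <- function(poly) {
  abs(ring_signed_area(project_sinusoidal(poly)))
}

#' Clip a polygon by a convex polygon (Sutherland-Hodgman)
#'
#' Exact for any simple subject polygon when the clip polygon is convex;
#' the realm tiles and synthetic mountain polygons used in this package are
#' convex by construction.
#'
#' @param subject two-column matrix (open ring).
#' @param clip two-column matrix (open ring) of a convex polygon.
#' @return a two-column matrix (possibly with 0 rows when disjoint).
#' @export
clip_polygon_convex <- function(subject, clip) {
  if (ring_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    # inside = left of (or on) the directed edge a->b
    cross_ab <- function(px, py)
      (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    n <- nrow(out)
    res_x <- numeric(0); res_y <- numeric(0)
    d <- cross_ab(out[, 1], out[, 2])
    for (j in seq_len(n)) {
      k <- if (j == n) 1 else j + 1
      cur_in <- d[j] >= 0; nxt_in <- d[k] >= 0
      if (cur_in) { res_x <- c(res_x, out[j, 1]); res_y <- c(res_y, out[j, 2]) }
      if (xor(cur_in, nxt_in)) {
        t <- d[j] / (d[j] - d[k])
        res_x <- c(res_x, out[j, 1] + t * (out[k, 1] - out[j, 1]))
        res_y <- c(res_y, out[j, 2] + t * (out[k, 2] - out[j, 2]))
      }
    }
    out <- cbind(res_x, res_y)
  }
  dimnames(out) <- NULL
  out
}

#' Area of intersection of two polygons, in km^2
#'
#' @param p1 subject polygon (any simple ring).
#' @param p2 convex polygon.
#' @return intersection area in km^2 (0 when disjoint).
#' @export
intersection_area_km2 <- function(p1, p2) {
  # cheap reject on bounding boxes
  if (min(p1[, 1]) > max(p2[, 1]) || max(p1[, 1]) < min(p2[, 1]) ||
      min(p1[, 2]) > max(p2[, 2]) || max(p1[, 2]) < min(p2[, 2])) return(0)
  inter <- clip_polygon_convex(p1, p2)
  if (nrow(inter) < 3) return(0)
  polygon_area_km2(inter)
}

#' Great-circle (haversine) distance in km
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectors recycle.
#' @return distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Minimum great-circle distance (km) from a polygon to each of a set of points
#'
#' The distance is 0 for points inside the polygon (the polygon interior
#' counts); otherwise the minimum over the polygon boundary, with the nearest
#' boundary location found by projecting onto each edge in a local
#' equirectangular frame.
#'
#' @param poly two-column (lon, lat) matrix.
#' @param lon,lat point coordinates.
#' @return numeric vector of distances in km.
#' @export
dist_poly_points_km <- function(poly, lon, lat) {
  n <- length(lon)
  out <- numeric(n)
  inside <- point_in_poly(lon, lat, poly)
  nv <- nrow(poly)
  nxt <- c(seq_len(nv)[-1], 1)
  for (i in seq_len(n)) {
    if (inside[i]) next
    cl <- cos(lat[i] * pi / 180)
    px <- (poly[, 1] - lon[i]) * KM_PER_DEG * cl
    py <- (poly[, 2] - lat[i]) * KM_PER_DEG
    ax <- px; ay <- py; bx <- px[nxt]; by <- py[nxt]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0, pmin(1, pmax(0, -(ax * dx + ay * dy) / len2)), 0)
    qx <- ax + t * dx; qy <- ay + t * dy
    out[i] <- sqrt(min(qx^2 + qy^2))
  }
  out
}

#' Convex polygon from random points in a disc
#'
#' Utility used by the synthetic world generator: the convex hull of `k`
#' points drawn uniformly in a disc of radius `r` around `center`.
#'
#' @param center length-2 numeric (lon, lat).
#' @param r disc radius in degrees.
#' @param k number of points to draw.
#' @return a two-column matrix (open ring, counterclockwise).
#' @export
random_convex_polygon <- function(center, r, k = 12) {
  ang <- runif(k, 0, 2 * pi)
  rad <- r * sqrt(runif(k))
  x <- center[1] + rad * cos(ang)
  y <- center[2] + rad * sin(ang)
  h <- grDevices::chull(x, y)      # clockwise order
  cbind(x[rev(h)], y[rev(h)])
}

# pairwise-disjointness check for a polygon layer; returns offending id pairs
find_overlapping_pairs <- function(layer, tol_km2 = 1e-9) {
  ids <- layer_ids(layer)
  bad <- list()
  n <- length(ids)
  if (n < 2) return(bad)
  bb <- t(vapply(layer$geoms, function(g)
    c(min(g[, 1]), max(g[, 1]), min(g[, 2]), max(g[, 2])), numeric(4)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bb[i, 1] > bb[j, 2] || bb[i, 2] < bb[j, 1] ||
        bb[i, 3] > bb[j, 4] || bb[i, 4] < bb[j, 3]) next
    a <- intersection_area_km2(layer$geoms[[ids[i]]], layer$geoms[[ids[j]]])
    if (a > tol_km2) bad[[length(bad) + 1]] <- c(ids[i], ids[j])
  }
  bad
}
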