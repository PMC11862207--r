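# GeoJSON and CSV readers/writers for the pipeline's exchange formats.
#
# GeoJSON is written/parsed with jsonlite directly: polygon layers become
# FeatureCollections of Polygon features (single outer ring), point tables
# FeatureCollections of Point features.  Occurrence CSVs use the
# Darwin-Core-flavoured column names `decimalLongitude`/`decimalLatitude`.

close_ring <- function(m) rbind(m, m[1, , drop = FALSE])

#' Write a polygon layer to GeoJSON
#'
#' @param layer an [ovd_layer].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_geojson_polygons <- function(layer, path) {
  ids <- layer_ids(layer)
  feats <- lapply(seq_along(ids), function(i) {
    ring <- close_ring(layer$geoms[[ids[i]]])
    props <- as.list(layer$data[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polygon layer from GeoJSON
#'
#' Only single-ring Polygon features are supported (the package never writes
#' anything else).
#'
#' @param path GeoJSON file.
#' @param id_col property used as the feature id.
#' @return an [ovd_layer].
#' @export
read_geojson_polygons <- function(path, id_col = NULL) {
  js <- jsonlite::read_json(path)
  if (!identical(js$type, "FeatureCollection"))
    stop_oro("not a GeoJSON FeatureCollection: ", path)
  props <- lapply(js$features, function(f)
    lapply(f$properties, function(v) if (is.null(v)) NA else v))
  data <- do.call(rbind, lapply(props, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  id_col <- id_col %||% names(data)[1]
  geoms <- lapply(js$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop_oro("unsupported geometry type: ", f$geometry$type)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
  })
  names(geoms) <- as.character(data[[id_col]])
  ovd_layer(geoms, data, id_col)
}

#' Write / read a point table as GeoJSON
#'
#' @param pts data.frame with `lon` and `lat` columns plus attributes.
#' @param path file path.
#' @return `read_geojson_points` returns a data.frame.
#' @export
write_geojson_points <- function(pts, path) {
  attrs <- setdiff(names(pts), c("lon", "lat"))
  feats <- lapply(seq_len(nrow(pts)), function(i) {
    list(type = "Feature",
         properties = as.list(pts[i, attrs, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(pts$lon[i], pts$lat[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_points
#' @export
read_geojson_points <- function(path) {
  js <- jsonlite::read_json(path)
  coords <- do.call(rbind, lapply(js$features, function(f)
    as.numeric(unlist(f$geometry$coordinates))))
  props <- do.call(rbind, lapply(js$features, function(f)
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)))
  out <- cbind(props, data.frame(lon = coords[, 1], lat = coords[, 2]))
  rownames(out) <- NULL
  out
}

#' Write / read occurrence records CSV
#'
#' External column dialect: `record_id, species_id, class, decimalLongitude,
#' decimalLatitude`; internally the package uses `taxon_class`, `lon`, `lat`.
#'
#' @param records internal-format records data.frame.
#' @param path CSV path.
#' @return `read_occurrences_csv` returns an internal-format data.frame.
#' @export
write_occurrences_csv <- function(records, path) {
  df <- data.frame(record_id = records$record_id,
                   species_id = records$species_id,
                   class = records$taxon_class,
                   decimalLongitude = records$lon,
                   decimalLatitude = records$lat)
  extra <- setdiff(names(records),
                   c("record_id", "species_id", "taxon_class", "lon", "lat"))
  if (length(extra)) df <- cbind(df, records[extra])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "class", "decimalLongitude", "decimalLatitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_oro("occurrence CSV is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    record_id = if ("record_id" %in% names(df)) df$record_id
                else sprintf("rec%06d", seq_len(nrow(df))),
    species_id = df$species_id,
    taxon_class = df$class,
    lon = df$decimalLongitude,
    lat = df$decimalLatitude,
    stringsAsFactors = FALSE)
  validate_records(out)
  out
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("record_id", "species_id", "taxon_class", "lon", "lat")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_oro("records are missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$lon < -180 | records$lon > 180, na.rm = TRUE) ||
      any(records$lat < -90 | records$lat > 90, na.rm = TRUE))
    stop_oro("record coordinates outside WGS84 bounds")
  bad <- setdiff(unique(records$taxon_class), TAXON_CLASSES)
  if (length(bad))
    stop_oro("unknown taxon class(es): ", paste(bad, collapse = ", "))
  invisible(records)
}

#' Write species ranges to GeoJSON
#'
#' One Polygon feature per native polygon, with `species_id`, `taxon_class`
#' and `part` properties; species may contribute several features.
#'
#' @param species species range set (see [generate_world]).
#' @param path file path.
#' @return `read_ranges_geojson` returns a species range list.
#' @export
write_ranges_geojson <- function(species, path) {
  feats <- list()
  for (sp in species) {
    for (k in seq_along(sp$native_polygons)) {
      ring <- close_ring(sp$native_polygons[[k]])
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(species_id = sp$species_id,
                          taxon_class = sp$taxon_class, part = k),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(j) ring[j, ]))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ranges_geojson
#' @export
read_ranges_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  out <- list()
  for (f in js$features) {
    sid <- f$properties$species_id
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    ring <- ring[-nrow(ring), , drop = FALSE]
    if (is.null(out[[sid]]))
      out[[sid]] <- list(species_id = sid,
                         taxon_class = f$properties$taxon_class,
                         native_polygons = list())
    out[[sid]]$native_polygons[[length(out[[sid]]$native_polygons) + 1]] <- ring
  }
  out
}
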