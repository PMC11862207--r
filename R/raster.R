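# Minimal single-band raster and monthly raster-stack containers.
#
# A raster is a numeric matrix plus a lon/lat extent; row 1 is the northmost
# row (the usual top-down image convention).  Cells are square in degrees.
# Plain-text I/O uses the ESRI ASCII grid format so that fixtures and outputs
# stay human-readable.

#' Construct a raster
#'
#' @param values numeric matrix; row 1 = northmost row.
#' @param extent numeric of length 4: xmin, xmax, ymin, ymax (degrees).
#' @return an object of class `ovd_raster`.
#' @export
ovd_raster <- function(values, extent) {
  stopifnot(is.matrix(values), length(extent) == 4)
  extent <- as.numeric(extent)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop_oro("degenerate raster extent")
  resx <- (extent[2] - extent[1]) / ncol(values)
  resy <- (extent[4] - extent[3]) / nrow(values)
  if (abs(resx - resy) > 1e-9)
    stop_oro("raster cells must be square in degrees")
  structure(list(values = values, xmin = extent[1], xmax = extent[2],
                 ymin = extent[3], ymax = extent[4], res = resx),
            class = "ovd_raster")
}

#' @export
print.ovd_raster <- function(x, ...) {
  cat(sprintf("<ovd_raster %d x %d, res %.4g deg, extent [%g,%g]x[%g,%g]>\n",
              nrow(x$values), ncol(x$values), x$res,
              x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

#' Cell-center coordinates of a raster
#'
#' @param r an [ovd_raster].
#' @return list with `x` (by column) and `y` (by row, north to south).
#' @export
raster_centers <- function(r) {
  list(x = r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$res,
       y = r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$res)
}

#' Indices of cells whose center falls inside a polygon (center rule)
#'
#' @param r an [ovd_raster].
#' @param poly two-column (lon, lat) matrix.
#' @return integer matrix with columns `row`, `col`.
#' @export
cells_in_polygon <- function(r, poly) {
  cc <- raster_centers(r)
  cols <- which(cc$x >= min(poly[, 1]) & cc$x <= max(poly[, 1]))
  rows <- which(cc$y >= min(poly[, 2]) & cc$y <= max(poly[, 2]))
  if (!length(cols) || !length(rows))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  grid <- expand.grid(row = rows, col = cols)
  inside <- point_in_poly(cc$x[grid$col], cc$y[grid$row], poly)
  as.matrix(grid[inside, , drop = FALSE])
}

#' Zonal mean of a raster over the polygons of a layer
#'
#' Averages the values of all cells whose center falls inside each polygon;
#' `NA` cells are dropped. Polygons intersecting no cell get `NA` (reported
#' via the `n_cells` column).
#'
#' @param r an [ovd_raster].
#' @param layer an [ovd_layer].
#' @return data.frame with id, `mean` and `n_cells`.
#' @export
zonal_mean <- function(r, layer) {
  ids <- layer_ids(layer)
  out <- data.frame(id = ids, mean = NA_real_, n_cells = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    idx <- cells_in_polygon(r, layer$geoms[[ids[i]]])
    if (nrow(idx) == 0) next
    v <- r$values[idx]
    out$n_cells[i] <- sum(!is.na(v))
    if (out$n_cells[i] > 0) out$mean[i] <- mean(v, na.rm = TRUE)
  }
  names(out)[1] <- layer$id_col
  out
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' @param r an [ovd_raster].
#' @param path file path.
#' @param digits significant digits written.
#' @return `read_asc` returns an [ovd_raster]; `write_asc` its path,
#'   invisibly.
#' @export
write_asc <- function(r, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$res),
    "NODATA_value -9999"), con)
  v <- r$values
  v[is.na(v)] <- -9999
  writeLines(apply(formatC(v, format = "g", digits = digits), 1, paste,
                   collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                   tolower(vapply(kv, `[`, "", 1)))
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == vals["nodata_value"]] <- NA
  ovd_raster(m, c(vals["xllcorner"],
                  vals["xllcorner"] + vals["ncols"] * vals["cellsize"],
                  vals["yllcorner"],
                  vals["yllcorner"] + vals["nrows"] * vals["cellsize"]))
}

#' Construct a monthly raster stack
#'
#' @param values 3-d array `[row, col, layer]`, row 1 = northmost.
#' @param year,month integer vectors, one entry per layer.
#' @param extent numeric length 4: xmin, xmax, ymin, ymax.
#' @return an object of class `ovd_stack`.
#' @export
ovd_stack <- function(values, year, month, extent) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[3] == length(year), length(year) == length(month))
  r1 <- ovd_raster(values[, , 1, drop = TRUE], extent)  # validates extent
  structure(list(values = values, year = as.integer(year),
                 month = as.integer(month),
                 xmin = r1$xmin, xmax = r1$xmax, ymin = r1$ymin,
                 ymax = r1$ymax, res = r1$res),
            class = "ovd_stack")
}

#' @export
print.ovd_stack <- function(x, ...) {
  cat(sprintf("<ovd_stack %d x %d x %d layers, %d-%d>\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$year), max(x$year)))
  invisible(x)
}

# one band of a stack as a raster
stack_band <- function(s, k) {
  ovd_raster(s$values[, , k, drop = TRUE], c(s$xmin, s$xmax, s$ymin, s$ymax))
}

#' Write / read a climate stack as long-format CSV
#'
#' Columns: year, month, row, col, value. A small JSON header file
#' (`<path>.meta.json`) carries the extent.
#'
#' @param s an [ovd_stack].
#' @param path CSV file path.
#' @return `read_stack_csv` returns an [ovd_stack].
#' @export
write_stack_csv <- function(s, path) {
  nl <- dim(s$values)[3]
  nr <- dim(s$values)[1]; nc <- dim(s$values)[2]
  df <- data.frame(
    year = rep(s$year, each = nr * nc),
    month = rep(s$month, each = nr * nc),
    row = rep(rep(seq_len(nr), nc), nl),
    col = rep(rep(seq_len(nc), each = nr), nl),
    value = as.vector(s$values))
  data.table::fwrite(df, path)
  jsonlite::write_json(list(xmin = s$xmin, xmax = s$xmax, ymin = s$ymin,
                            ymax = s$ymax, nrow = nr, ncol = nc),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- as.data.frame(data.table::fread(path))
  key <- paste(df$year, df$month)
  layers <- unique(key)
  arr <- array(NA_real_, c(meta$nrow, meta$ncol, length(layers)))
  arr[cbind(df$row, df$col, match(key, layers))] <- df$value
  ym <- do.call(rbind, strsplit(layers, " "))
  ovd_stack(arr, as.integer(ym[, 1]), as.integer(ym[, 2]),
            c(meta$xmin, meta$xmax, meta$ymin, meta$ymax))
}
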