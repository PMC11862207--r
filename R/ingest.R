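# Occurrence ingestion: mountain assignment, the spatially explicit
# alien-status filter against native ranges, richness/record-density tables,
# and sampling-completeness residuals.

#' Assign occurrence records to mountains
#'
#' Records whose point lies inside a mountain polygon (boundary inclusive)
#' get its `mountain_id`; points on a shared border go to the
#' lexicographically smallest id; all other records are marked unassigned
#' (`NA`) and are excluded by downstream per-mountain summaries.
#'
#' @param records occurrence data.frame (`record_id`, `species_id`,
#'   `taxon_class`, `lon`, `lat`).
#' @param mountains an [ovd_layer] of pairwise disjoint mountain polygons.
#' @param check_overlap validate disjointness first (costs one all-pairs
#'   sweep; disable for repeated calls on a validated layer).
#' @return `records` with a `mountain_id` column added.
#' @export
assign_mountain <- function(records, mountains, check_overlap = TRUE) {
  validate_records(records)
  if (check_overlap) {
    bad <- find_overlapping_pairs(mountains)
    if (length(bad))
      stop_oro("mountain polygons overlap: ",
               paste(vapply(bad, paste, "", collapse = "/"), collapse = ", "))
  }
  records$mountain_id <- locate_points(records$lon, records$lat, mountains)
  records
}

#' Spatially explicit alien-status filter
#'
#' A record is discarded exactly when its point falls inside any native-range
#' polygon of its own species; all other records are kept and flagged
#' `alien = TRUE`. Records of species absent from the range set are kept but
#' flagged `range_known = FALSE` (the upstream checklists already classed
#' them as alien; the flag lets users drop them instead).
#'
#' @param records occurrence data.frame.
#' @param ranges named list (by species id) with `native_polygons` entries,
#'   e.g. `world$species` or [read_ranges_geojson] output.
#' @return list with `kept`, `discarded`, and `n_range_unknown`.
#' @export
filter_native_overlap <- function(records, ranges) {
  validate_records(records)
  discard <- rep(FALSE, nrow(records))
  range_known <- rep(TRUE, nrow(records))
  for (sid in unique(records$species_id)) {
    i <- which(records$species_id == sid)
    rg <- ranges[[sid]]
    if (is.null(rg) || !length(rg$native_polygons)) {
      range_known[i] <- FALSE
      next
    }
    inside <- rep(FALSE, length(i))
    for (np in rg$native_polygons)
      inside <- inside | point_in_poly(records$lon[i], records$lat[i], np)
    discard[i] <- inside
  }
  n_unknown <- sum(range_known == FALSE)
  if (n_unknown > 0)
    warn_oro(n_unknown, " record(s) of species without native-range data ",
             "kept with range_known = FALSE")
  kept <- records[!discard, , drop = FALSE]
  kept$alien <- TRUE
  kept$range_known <- range_known[!discard]
  rownames(kept) <- NULL
  discarded <- records[discard, , drop = FALSE]
  rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded, n_range_unknown = n_unknown)
}

#' Per-mountain alien richness and record density
#'
#' Counts distinct species and records per mountain, overall and per taxon
#' class, and divides record counts by the mountain's inventory area (the
#' `area_km2` attribute -- never recomputed from the polygon). Mountains with
#' no kept record are omitted.
#'
#' @param kept alien-filtered records carrying `mountain_id`.
#' @param mountains an [ovd_layer] with an `area_km2` column.
#' @return data.frame: `mountain_id`, `scope` (taxon class or `"all"`),
#'   `n_species`, `n_records`, `record_density` (records/km^2).
#' @export
richness_table <- function(kept, mountains) {
  if (!"mountain_id" %in% names(kept))
    stop_oro("records must be assigned to mountains first")
  kept <- kept[!is.na(kept$mountain_id), , drop = FALSE]
  empty <- data.frame(mountain_id = character(0), scope = character(0),
                      n_species = integer(0), n_records = integer(0),
                      record_density = numeric(0))
  if (nrow(kept) == 0) return(empty)
  area <- setNames(mountains$data$area_km2, layer_ids(mountains))
  one_scope <- function(df, scope) {
    if (nrow(df) == 0) return(empty)
    nr <- aggregate(record_id ~ mountain_id, df, length)
    ns <- aggregate(species_id ~ mountain_id,
                    unique(df[c("mountain_id", "species_id")]), length)
    out <- merge(ns, nr, by = "mountain_id")
    data.frame(mountain_id = out$mountain_id, scope = scope,
               n_species = out$species_id, n_records = out$record_id,
               record_density = out$record_id / unname(area[out$mountain_id]))
  }
  parts <- c(list(one_scope(kept, "all")),
             lapply(intersect(TAXON_CLASSES, unique(kept$taxon_class)),
                    function(cl)
                      one_scope(kept[kept$taxon_class == cl, ], cl)))
  out <- do.call(rbind, parts)
  out <- out[order(out$mountain_id, out$scope), ]
  rownames(out) <- NULL
  out
}

#' Residual alien richness after accounting for sampling completeness
#'
#' Ordinary least-squares regression of per-mountain alien richness on mean
#' sampling completeness; positive residuals mark mountains with more alien
#' species than their sampling effort predicts. With (near-)constant
#' completeness the fit degenerates to an intercept-only model (residual =
#' deviation from the mean), with a warning.
#'
#' @param richness data.frame with `mountain_id` and `n_species` (one row per
#'   mountain, e.g. the `scope == "all"` rows of [richness_table]).
#' @param completeness data.frame with `mountain_id` and `completeness`.
#' @return data.frame: `mountain_id`, `n_species`, `completeness`, `fitted`,
#'   `residual`.
#' @export
completeness_residuals <- function(richness, completeness) {
  df <- merge(richness[c("mountain_id", "n_species")],
              completeness[c("mountain_id", "completeness")],
              by = "mountain_id")
  if (nrow(df) < 3) stop_oro("need >= 3 mountains for a regression")
  if (sd(df$completeness) < 1e-12) {
    warn_oro("constant completeness; falling back to intercept-only model")
    df$fitted <- mean(df$n_species)
  } else {
    df$fitted <- fitted(lm(n_species ~ completeness, data = df))
  }
  df$residual <- df$n_species - df$fitted
  df
}
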