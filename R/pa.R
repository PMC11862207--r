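# Protected-area incidence of alien records: WDPA-style status/category
# filtering, record-PA overlap, and per-category / per-realm summaries with
# mountain-portion area correction.

PA_KEEP_STATUS <- c("designated", "inscribed", "established")
IUCN_CATEGORIES <- c("Ia", "Ib", "II", "III", "IV", "V", "VI")
UNASSIGNED_CATEGORY <- c("", "not reported", "not assigned", "not applicable",
                         "unassigned", NA)

#' Filter protected areas by status and IUCN category
#'
#' Keeps PAs whose status is designated, inscribed or established
#' (case-insensitive) and that carry an assigned IUCN category Ia-VI. WDPA
#' dialect values "Not Reported"/"Not Assigned"/"Not Applicable" count as
#' unassigned.
#'
#' @param pas an [ovd_layer] with `status` and `iucn_category` columns.
#' @return the filtered [ovd_layer]; rejected rows (with a `reason`) are
#'   attached as attribute `"rejected"`.
#' @export
filter_pas <- function(pas) {
  d <- pas$data
  if (!all(c("status", "iucn_category") %in% names(d)))
    stop_oro("PA layer must have `status` and `iucn_category` columns")
  status_ok <- tolower(trimws(d$status)) %in% PA_KEEP_STATUS
  cat_ok <- !(tolower(trimws(d$iucn_category)) %in%
              tolower(UNASSIGNED_CATEGORY) | is.na(d$iucn_category)) &
            d$iucn_category %in% IUCN_CATEGORIES
  keep <- status_ok & cat_ok
  rejected <- d[!keep, , drop = FALSE]
  rejected$reason <- ifelse(!status_ok[!keep], "status not kept",
                            "IUCN category unassigned")
  ids <- layer_ids(pas)[keep]
  out <- ovd_layer(pas$geoms[ids], d[keep, , drop = FALSE], pas$id_col)
  attr(out, "rejected") <- rejected
  out
}

#' Overlap alien records with protected areas
#'
#' A record inside one or more kept PAs yields one annotation row per
#' containing PA (nested PAs each count); records outside all PAs do not
#' appear.
#'
#' @param kept alien-filtered records.
#' @param pas a filtered PA [ovd_layer] (see [filter_pas]).
#' @return data.frame: all record columns plus `pa_id` and `iucn_category`,
#'   one row per (record, containing PA) pair.
#' @export
pa_overlap <- function(kept, pas) {
  validate_records(kept)
  ids <- layer_ids(pas)
  cat_of <- setNames(pas$data$iucn_category, ids)
  out <- list()
  for (id in ids) {
    g <- pas$geoms[[id]]
    cand <- which(kept$lon >= min(g[, 1]) & kept$lon <= max(g[, 1]) &
                  kept$lat >= min(g[, 2]) & kept$lat <= max(g[, 2]))
    if (!length(cand)) next
    inside <- cand[point_in_poly(kept$lon[cand], kept$lat[cand], g)]
    if (!length(inside)) next
    ann <- kept[inside, , drop = FALSE]
    ann$pa_id <- id
    ann$iucn_category <- unname(cat_of[id])
    out[[id]] <- ann
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(kept[0, , drop = FALSE],
          data.frame(pa_id = character(0), iucn_category = character(0)))
  rownames(res) <- NULL
  res
}

#' Mountain-portion area of each protected area
#'
#' Sum over mountains of the equal-area intersection of the PA polygon with
#' the mountain polygon, in km^2 (mountain polygons must be convex, as the
#' synthetic inventory guarantees).
#'
#' @param pas a PA [ovd_layer].
#' @param mountains a mountain [ovd_layer].
#' @return named numeric vector of km^2 per pa_id.
#' @export
pa_mountain_area <- function(pas, mountains) {
  vapply(layer_ids(pas), function(pid) {
    g <- pas$geoms[[pid]]
    sum(vapply(mountains$geoms, function(m)
      intersection_area_km2(g, m), 0))
  }, 0)
}

#' Per-category and per-realm summaries of alien records in protected areas
#'
#' Within a category, species are counted once; records are counted once per
#' containing PA (the overlap table's convention). Area-corrected densities
#' divide by the summed mountain-portion area of the category's PAs;
#' categories with zero mountain-portion area get `NA` densities (undefined,
#' not infinite).
#'
#' @param overlap output of [pa_overlap].
#' @param pas the filtered PA [ovd_layer].
#' @param mountains mountain [ovd_layer] (for the area correction).
#' @param realms realm [ovd_layer]; the realm of an annotation is the realm
#'   containing the record's point.
#' @return list with `by_category`, `by_realm_category`, and
#'   `species_only_in_pas` (ids of species all of whose kept records lie in
#'   PAs, when `kept_records` is supplied).
#' @param kept_records optional full kept-record table used for the
#'   species-exclusivity summary.
#' @export
pa_summaries <- function(overlap, pas, mountains, realms,
                         kept_records = NULL) {
  area_by_pa <- pa_mountain_area(pas, mountains)
  cat_area <- tapply(area_by_pa, pas$data$iucn_category, sum)
  cats <- sort(unique(pas$data$iucn_category))
  by_cat <- do.call(rbind, lapply(cats, function(cl) {
    sub <- overlap[overlap$iucn_category == cl, , drop = FALSE]
    a <- unname(cat_area[cl])
    per_class <- vapply(TAXON_CLASSES, function(tc)
      length(unique(sub$species_id[sub$taxon_class == tc])), 0L)
    data.frame(iucn_category = cl,
               n_records = nrow(sub),
               n_species = length(unique(sub$species_id)),
               t(per_class),
               area_km2 = a,
               records_per_km2 = if (isTRUE(a > 0)) nrow(sub) / a else NA_real_,
               species_per_km2 = if (isTRUE(a > 0))
                 length(unique(sub$species_id)) / a else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_cat) <- NULL

  ov <- overlap
  ov$realm_id <- locate_points(ov$lon, ov$lat, realms)
  ov <- ov[!is.na(ov$realm_id), , drop = FALSE]
  by_rc <- if (nrow(ov)) {
    u <- unique(ov[c("realm_id", "iucn_category", "species_id")])
    agg <- aggregate(species_id ~ realm_id + iucn_category, u, length)
    names(agg)[3] <- "n_species"
    agg[order(agg$realm_id, agg$iucn_category), ]
  } else data.frame(realm_id = character(0), iucn_category = character(0),
                    n_species = integer(0))
  rownames(by_rc) <- NULL

  only_in_pas <- NULL
  if (!is.null(kept_records)) {
    in_pa <- unique(overlap$record_id)
    sp_all <- split(kept_records$record_id, kept_records$species_id)
    only_in_pas <- names(sp_all)[vapply(sp_all, function(r)
      all(r %in% in_pa), TRUE)]
  }
  list(by_category = by_cat, by_realm_category = by_rc,
       species_only_in_pas = only_in_pas)
}
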