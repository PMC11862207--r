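# Donor -> recipient realm flow matrices of alien species and the
# resampling null model that tests each flow against the global native pool.

#' Annotate ranges with native realms and records with recipient realms
#'
#' A species' native realms are all realms its native polygons intersect; a
#' record's recipient realm is the realm containing its point. Records
#' outside every realm are excluded with a warning.
#'
#' @param ranges named species range list (`native_polygons` per species).
#' @param realms an [ovd_layer] of realm polygons covering the study extent
#'   (the Voronoi tiles of the synthetic world are convex, as required by the
#'   polygon intersection used here).
#' @param records occurrence data.frame.
#' @return list with `ranges` (each gaining `native_realms`) and `records`
#'   (gaining `realm_id`, rows outside all realms dropped).
#' @export
assign_realms <- function(ranges, realms, records) {
  realm_ids <- layer_ids(realms)
  for (sid in names(ranges)) {
    rng <- ranges[[sid]]
    nr <- realm_ids[vapply(realm_ids, function(rid)
      any(vapply(rng$native_polygons, function(np)
        intersection_area_km2(np, realms$geoms[[rid]]) > 1e-9, TRUE)), TRUE)]
    ranges[[sid]]$native_realms <- nr
  }
  records$realm_id <- locate_points(records$lon, records$lat, realms)
  n_out <- sum(is.na(records$realm_id))
  if (n_out > 0) {
    warn_oro(n_out, " record(s) outside all realms excluded")
    records <- records[!is.na(records$realm_id), , drop = FALSE]
  }
  list(ranges = ranges, records = records)
}

#' Donor x recipient realm flow matrix of alien species
#'
#' A species with native realms D and alien records in recipient realms R
#' contributes one count to every cell (d, r), d in D, r in R; intra-realm
#' (diagonal) flows are legitimate. The per-recipient number of distinct
#' alien species (the resampling sizes for [null_flow_test]) is stored as
#' well.
#'
#' @param kept alien-filtered records with `realm_id`.
#' @param ranges species ranges with `native_realms` (see [assign_realms]).
#' @param realms an [ovd_layer] (fixes the realm ordering).
#' @param taxon a taxon class, or `"all"`.
#' @return an object of class `flow_matrix`: `realms`, `counts`
#'   (donor x recipient), `taxon`, `n_species_by_recipient`.
#' @export
flow_matrix <- function(kept, ranges, realms, taxon = "all") {
  realm_ids <- layer_ids(realms)
  if (!identical(taxon, "all")) {
    if (!taxon %in% TAXON_CLASSES) stop_oro("unknown taxon class: ", taxon)
    kept <- kept[kept$taxon_class == taxon, , drop = FALSE]
  }
  counts <- matrix(0L, length(realm_ids), length(realm_ids),
                   dimnames = list(donor = realm_ids, recipient = realm_ids))
  k_r <- setNames(integer(length(realm_ids)), realm_ids)
  for (sid in unique(kept$species_id)) {
    rec <- unique(kept$realm_id[kept$species_id == sid])
    rec <- rec[!is.na(rec)]
    don <- ranges[[sid]]$native_realms
    if (!length(rec) || is.null(don) || !length(don)) next
    counts[don, rec] <- counts[don, rec] + 1L
    k_r[rec] <- k_r[rec] + 1L
  }
  structure(list(realms = realm_ids, counts = counts, taxon = taxon,
                 n_species_by_recipient = k_r),
            class = "flow_matrix")
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat(sprintf("<flow_matrix (%s): %d realms, %d species-flows>\n",
              x$taxon, length(x$realms), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Resampling null test for realm flows
#'
#' For each recipient realm r with k_r observed alien species, every draw
#' samples k_r species without replacement from the global pool and tallies
#' their native-realm composition (multi-realm natives count once towards
#' each of their native realms, mirroring the observed matrix). An observed
#' cell is `higher`/`lower` when it is at or beyond the upper/lower 2.5%
#' order statistic of the `n_draws` draws.
#'
#' @param observed a [flow_matrix].
#' @param pool data.frame of the global species pool: `species_id` plus
#'   `native_realms` (list column) or long format with a `realm_id` column;
#'   every pool species must have >= 1 native realm.
#' @param n_draws number of null draws.
#' @param seed integer seed.
#' @return data.frame (class `flow_null_test`): donor, recipient, observed,
#'   q025, q500, q975, verdict; attributes `n_draws` and `seed`.
#' @export
null_flow_test <- function(observed, pool, n_draws = 999, seed = 1L) {
  stopifnot(inherits(observed, "flow_matrix"))
  realm_ids <- observed$realms
  # normalise pool to a species -> native realm incidence matrix
  if ("realm_id" %in% names(pool)) {
    sp <- unique(pool$species_id)
    inc <- matrix(0L, length(sp), length(realm_ids),
                  dimnames = list(sp, realm_ids))
    inc[cbind(match(pool$species_id, sp), match(pool$realm_id, realm_ids))] <- 1L
  } else {
    sp <- pool$species_id
    inc <- matrix(0L, length(sp), length(realm_ids),
                  dimnames = list(sp, realm_ids))
    for (i in seq_along(sp)) inc[i, pool$native_realms[[i]]] <- 1L
  }
  if (any(rowSums(inc) == 0))
    stop_oro("every pool species must carry >= 1 native realm")
  n_pool <- nrow(inc)
  set.seed(seed)
  out <- list()
  for (r in realm_ids) {
    k_r <- observed$n_species_by_recipient[[r]]
    if (k_r > n_pool)
      stop_oro("recipient ", r, ": observed species count ", k_r,
               " exceeds pool size ", n_pool)
    draws <- matrix(0L, n_draws, length(realm_ids),
                    dimnames = list(NULL, realm_ids))
    if (k_r > 0) {
      for (b in seq_len(n_draws))
        draws[b, ] <- colSums(inc[sample.int(n_pool, k_r), , drop = FALSE])
    }
    lo <- apply(draws, 2, quantile, probs = 0.025, type = 1)
    md <- apply(draws, 2, quantile, probs = 0.5, type = 1)
    hi <- apply(draws, 2, quantile, probs = 0.975, type = 1)
    obs <- observed$counts[, r]
    # "in or beyond" the 2.5% tails: at the order statistic counts as beyond;
    # a fully degenerate null (q025 == q975 == obs) stays ns
    verdict <- ifelse(obs >= hi & obs > lo, "higher",
                      ifelse(obs <= lo & obs < hi, "lower", "ns"))
    out[[r]] <- data.frame(donor = realm_ids, recipient = r,
                           observed = as.integer(obs), q025 = lo, q500 = md,
                           q975 = hi, verdict = verdict,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_draws") <- n_draws
  attr(res, "seed") <- seed
  attr(res, "taxon") <- observed$taxon
  attr(res, "taxon_specific_extension") <- !identical(observed$taxon, "all")
  class(res) <- c("flow_null_test", "data.frame")
  res
}

#' Long-format export of a flow matrix (chord-diagram input)
#'
#' @param fm a [flow_matrix].
#' @return data.frame `donor`, `recipient`, `count`, zero cells omitted.
#' @export
export_chord <- function(fm) {
  stopifnot(inherits(fm, "flow_matrix"))
  idx <- which(fm$counts > 0, arr.ind = TRUE)
  out <- data.frame(donor = fm$realms[idx[, 1]],
                    recipient = fm$realms[idx[, 2]],
                    count = fm$counts[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$donor, out$recipient), , drop = FALSE]
  rownames(out) <- NULL
  out
}
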