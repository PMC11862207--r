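# End-to-end orchestration: one YAML (or list) configuration drives the
# synth -> filter -> metrics -> flows / pa / fit stages, with a deterministic
# run manifest and JSON-lines stage logs.  All stage outputs are plain text
# (CSV / GeoJSON / ASCII grid / JSON), and re-running an unchanged config is
# byte-stable.

#' Default run configuration
#'
#' The analysis thresholds default to the published constants: dip > 0.01
#' with p < 0.05 for the hourglass rule, |skewness| >= 0.5 for the
#' pyramid/inverse-pyramid split, |r| > 0.7 for the collinearity screen, and
#' 999 resampling draws with 2.5% tails for the flow null model.
#'
#' @param out_dir output directory.
#' @param seed root seed; every stage derives a named sub-stream.
#' @param overrides named list merged over the defaults (nested lists merge
#'   one level deep).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = "oroinvade_run", seed = 1L,
                       overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(synth = TRUE, filter = TRUE, metrics = TRUE,
                  flows = TRUE, pa = TRUE, fit = TRUE),
    world = list(n_realms = 6, n_mountains = 100, n_species_pool = 800),
    occurrences = list(alien_fraction = 0.3, records_per_species = 30),
    thresholds = list(dip = 0.01, dip_p = 0.05, skew = 0.5, cor = 0.7,
                      n_draws = 999),
    fit = list(taxon_models = FALSE))
  for (k in names(overrides)) {
    if (is.list(overrides[[k]]) && is.list(cfg[[k]]))
      cfg[[k]] <- utils::modifyList(cfg[[k]], overrides[[k]])
    else cfg[[k]] <- overrides[[k]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys override [run_config] defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(out_dir = y$out_dir %||% "oroinvade_run",
             seed = y$seed %||% 1L,
             overrides = y[setdiff(names(y), c("out_dir", "seed"))])
}

#' Validate pipeline input files
#'
#' Schema and geometry checks per layer; fatal problems (unreadable file,
#' missing occurrence columns, overlapping mountains) are distinguished from
#' warnings (e.g. unknown PA status strings, which are merely excluded
#' downstream).
#'
#' @param paths named list with any of `occurrences`, `mountains`, `ranges`,
#'   `realms`, `pas` file paths.
#' @return data.frame `layer`, `level` (`fatal`/`warning`/`ok`), `message`.
#' @export
validate_inputs <- function(paths) {
  out <- list()
  note <- function(layer, level, msg)
    out[[length(out) + 1]] <<- data.frame(layer = layer, level = level,
                                          message = msg)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      note(nm, "fatal", paste("unreadable file:", paths[[nm]]))
    }
  }
  if (!is.null(paths$occurrences) && file.exists(paths$occurrences)) {
    rec <- try(read_occurrences_csv(paths$occurrences), silent = TRUE)
    if (inherits(rec, "try-error"))
      note("occurrences", "fatal", attr(rec, "condition")$message)
    else note("occurrences", "ok", paste(nrow(rec), "records"))
  }
  if (!is.null(paths$mountains) && file.exists(paths$mountains)) {
    mt <- try(read_geojson_polygons(paths$mountains), silent = TRUE)
    if (inherits(mt, "try-error")) {
      note("mountains", "fatal", attr(mt, "condition")$message)
    } else {
      bad <- find_overlapping_pairs(mt)
      if (length(bad))
        note("mountains", "fatal",
             paste("overlapping polygons:",
                   paste(vapply(bad, paste, "", collapse = "/"),
                         collapse = ", ")))
      else note("mountains", "ok", paste(length(mt$geoms), "polygons"))
    }
  }
  if (!is.null(paths$pas) && file.exists(paths$pas)) {
    pa <- try(read_geojson_polygons(paths$pas), silent = TRUE)
    if (inherits(pa, "try-error")) {
      note("pas", "fatal", attr(pa, "condition")$message)
    } else {
      unknown <- setdiff(tolower(trimws(unique(pa$data$status))),
                         c(PA_KEEP_STATUS, "proposed", "adopted"))
      if (length(unknown))
        note("pas", "warning",
             paste("unknown status string(s), rows excluded downstream:",
                   paste(unknown, collapse = ", ")))
      else note("pas", "ok", paste(length(pa$geoms), "polygons"))
    }
  }
  do.call(rbind, out)
}

log_stage <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full pipeline from one configuration
#'
#' Stages run in dependency order (synth, filter, metrics, flows, pa, fit);
#' turning a required upstream stage off makes downstream stages refuse with
#' a dependency error. All randomness derives from `config$seed` via named
#' sub-streams, so a rerun with the same config is byte-stable for every CSV
#' output. A `run_manifest.json` records package version, seeds, thresholds
#' and per-stage row counts; `run_log.jsonl` carries per-stage events.
#'
#' @param config a `run_config` (see [run_config] / [read_run_config]).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wdir <- file.path(cfg$out_dir, "world")
  log_con <- file(file.path(cfg$out_dir, "run_log.jsonl"), "w")
  on.exit(close(log_con))
  manifest <- list(package = "oroinvade",
                   version = as.character(utils::packageVersion("oroinvade")),
                   seed = cfg$seed, thresholds = cfg$thresholds,
                   stages_run = character(0), counts = list())
  need <- function(stage, f) {
    if (!file.exists(f))
      stop_oro("stage `", stage, "` requires missing input ", f,
               " (is its upstream stage toggled off?)")
    f
  }

  if (isTRUE(cfg$stages$synth)) {
    wc <- do.call(world_config, c(cfg$world, list(seed = cfg$seed)))
    world <- generate_world(
      wc, alien_fraction = cfg$occurrences$alien_fraction,
      records_per_species = cfg$occurrences$records_per_species)
    write_world(world, wdir)
    manifest$stages_run <- c(manifest$stages_run, "synth")
    manifest$counts$synth <- list(mountains = nrow(world$mountains$data),
                                  species = length(world$species),
                                  records = nrow(world$occurrences))
    log_stage(log_con, "synth", records = nrow(world$occurrences))
  }

  if (isTRUE(cfg$stages$filter)) {
    records <- read_occurrences_csv(need("filter", file.path(wdir, "occurrences.csv")))
    mountains <- read_geojson_polygons(need("filter", file.path(wdir, "mountains.geojson")))
    ranges <- read_ranges_geojson(need("filter", file.path(wdir, "native_ranges.geojson")))
    records <- assign_mountain(records, mountains)
    fl <- filter_native_overlap(records, ranges)
    rich <- richness_table(fl$kept, mountains)
    write_occurrences_csv(fl$kept, file.path(cfg$out_dir, "kept_records.csv"))
    write_occurrences_csv(fl$discarded, file.path(cfg$out_dir, "discarded_records.csv"))
    write.csv(rich, file.path(cfg$out_dir, "richness.csv"), row.names = FALSE)
    manifest$stages_run <- c(manifest$stages_run, "filter")
    manifest$counts$filter <- list(input = nrow(records),
                                   kept = nrow(fl$kept),
                                   discarded = nrow(fl$discarded),
                                   range_unknown = fl$n_range_unknown)
    log_stage(log_con, "filter", kept = nrow(fl$kept),
              discarded = nrow(fl$discarded))
  }

  if (isTRUE(cfg$stages$metrics)) {
    mountains <- read_geojson_polygons(need("metrics", file.path(wdir, "mountains.geojson")))
    dem <- read_asc(need("metrics", file.path(wdir, "dem.asc")))
    rasters <- lapply(setNames(nm = c("pop_density", "road_density", "bii",
                                      "completeness")),
                      function(nm) read_asc(file.path(wdir, paste0(nm, ".asc"))))
    climate <- read_stack_csv(need("metrics", file.path(wdir, "climate_tmin.csv")))
    cities <- read_geojson_points(file.path(wdir, "cities.geojson"))
    ports <- read_geojson_points(file.path(wdir, "ports.geojson"))
    vel <- gvocc(climate)
    pred <- extract_predictors(
      mountains, rasters, dem, vel$velocity, cities, ports,
      geometry_args = list(dip_threshold = cfg$thresholds$dip,
                           p_threshold = cfg$thresholds$dip_p,
                           skew_threshold = cfg$thresholds$skew))
    write.csv(pred, file.path(cfg$out_dir, "predictors.csv"), row.names = FALSE)
    jsonlite::write_json(attr(pred, "metadata"),
                         file.path(cfg$out_dir, "predictors_metadata.json"),
                         auto_unbox = TRUE)
    rich_path <- file.path(cfg$out_dir, "richness.csv")
    if (file.exists(rich_path)) {
      rich <- read.csv(rich_path)
      comp <- data.frame(mountain_id = pred$mountain_id,
                         completeness = pred$completeness)
      cres <- completeness_residuals(rich[rich$scope == "all", ], comp)
      write.csv(cres, file.path(cfg$out_dir, "completeness_residuals.csv"),
                row.names = FALSE)
    }
    manifest$stages_run <- c(manifest$stages_run, "metrics")
    manifest$counts$metrics <- list(mountains = nrow(pred))
    log_stage(log_con, "metrics", mountains = nrow(pred))
  }

  if (isTRUE(cfg$stages$flows)) {
    kept <- read_occurrences_csv(need("flows", file.path(cfg$out_dir, "kept_records.csv")))
    realms <- read_geojson_polygons(need("flows", file.path(wdir, "realms.geojson")))
    ranges <- read_ranges_geojson(need("flows", file.path(wdir, "native_ranges.geojson")))
    ar <- assign_realms(ranges, realms, kept)
    fm <- flow_matrix(ar$records, ar$ranges, realms, taxon = "all")
    pool <- data.frame(species_id = names(ar$ranges))
    pool$native_realms <- lapply(ar$ranges, `[[`, "native_realms")
    nt <- null_flow_test(fm, pool, n_draws = cfg$thresholds$n_draws,
                         seed = substream_seed(cfg$seed, "flows-null"))
    write.csv(as.data.frame(fm$counts),
              file.path(cfg$out_dir, "flow_matrix.csv"))
    write.csv(export_chord(fm), file.path(cfg$out_dir, "flow_chord.csv"),
              row.names = FALSE)
    nt_out <- as.data.frame(nt)
    nt_out$n_draws <- attr(nt, "n_draws"); nt_out$seed <- attr(nt, "seed")
    write.csv(nt_out, file.path(cfg$out_dir, "flow_null_test.csv"),
              row.names = FALSE)
    manifest$stages_run <- c(manifest$stages_run, "flows")
    manifest$counts$flows <- list(species_flows = sum(fm$counts))
    log_stage(log_con, "flows", species_flows = sum(fm$counts))
  }

  if (isTRUE(cfg$stages$pa)) {
    kept <- read_occurrences_csv(need("pa", file.path(cfg$out_dir, "kept_records.csv")))
    pas <- read_geojson_polygons(need("pa", file.path(wdir, "protected_areas.geojson")))
    mountains <- read_geojson_polygons(file.path(wdir, "mountains.geojson"))
    realms <- read_geojson_polygons(file.path(wdir, "realms.geojson"))
    kept_pas <- filter_pas(pas)
    ov <- pa_overlap(kept, kept_pas)
    sm <- pa_summaries(ov, kept_pas, mountains, realms, kept_records = kept)
    write.csv(sm$by_category, file.path(cfg$out_dir, "pa_by_category.csv"),
              row.names = FALSE)
    write.csv(sm$by_realm_category,
              file.path(cfg$out_dir, "pa_by_realm_category.csv"),
              row.names = FALSE)
    manifest$stages_run <- c(manifest$stages_run, "pa")
    manifest$counts$pa <- list(pas_kept = nrow(kept_pas$data),
                               overlapping_records = length(unique(ov$record_id)))
    log_stage(log_con, "pa", overlaps = nrow(ov))
  }

  if (isTRUE(cfg$stages$fit)) {
    pred <- read.csv(need("fit", file.path(cfg$out_dir, "predictors.csv")),
                     stringsAsFactors = FALSE)
    rich <- read.csv(need("fit", file.path(cfg$out_dir, "richness.csv")),
                     stringsAsFactors = FALSE)
    overall <- rich[rich$scope == "all", c("mountain_id", "n_species")]
    d <- merge(pred, overall, by = "mountain_id")  # >= 1 alien record
    numeric_preds <- c("pop_density", "road_density", "dist_cities",
                       "dist_ports", "bii", "gvocc_tmin", "roughness",
                       "elev_range", "completeness")
    scr <- collinearity_screen(d[numeric_preds],
                               threshold = cfg$thresholds$cor)
    use_num <- intersect(numeric_preds, scr$retained)
    cc <- complete.cases(d[c(use_num, "geometry")])
    d2 <- d[cc, , drop = FALSE]
    std <- standardize(d2[use_num])
    d2[use_num] <- std$data
    fit <- fit_nb_glmm(d2, c(use_num, "geometry"))
    write.csv(cbind(scope = "all", fit$coefficients),
              file.path(cfg$out_dir, "glmm_coefficients.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(theta = fit$theta, ranef_sd = as.list(fit$ranef_sd),
           n = fit$n, n_excluded_incomplete = sum(!cc),
           removed_collinear = scr$removed,
           converged = fit$converged, singular = fit$singular),
      file.path(cfg$out_dir, "glmm_random_effects.json"),
      auto_unbox = TRUE, digits = NA)
    if (isTRUE(cfg$fit$taxon_models)) {
      tm <- taxon_models(d[cc, , drop = FALSE], rich, c(use_num, "geometry"))
      tab <- do.call(rbind, lapply(names(tm), function(cl)
        if (!is.null(tm[[cl]])) cbind(scope = cl, tm[[cl]]$coefficients)))
      if (!is.null(tab))
        write.csv(tab, file.path(cfg$out_dir, "glmm_taxon_coefficients.csv"),
                  row.names = FALSE)
    }
    manifest$stages_run <- c(manifest$stages_run, "fit")
    manifest$counts$fit <- list(n_modelled = fit$n,
                                removed_collinear = scr$removed)
    log_stage(log_con, "fit", n = fit$n)
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
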