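pa_fixture <- function() {
  ovd_layer(
    list(P1 = square(0.2, 0.2, 1), P2 = square(0.5, 0.5, 1),
         P3 = square(5.2, 0.2, 1), P4 = square(6, 6, 1)),
    data.frame(pa_id = c("P1", "P2", "P3", "P4"),
               status = c("Designated", "designated", "Proposed", "Designated"),
               iucn_category = c("II", "V", "II", "Not Reported")))
}

test_that("status/category filtering follows the stated rules", {
  pas <- pa_fixture()
  kept <- filter_pas(pas)
  expect_setequal(names(kept$geoms), c("P1", "P2"))     # P3 proposed, P4 unassigned
  rej <- attr(kept, "rejected")
  expect_identical(rej$reason[rej$pa_id == "P3"], "status not kept")
  expect_identical(rej$reason[rej$pa_id == "P4"], "IUCN category unassigned")
  # established + assigned category is kept, case-insensitively
  pas2 <- pa_fixture()
  pas2$data$status[3] <- "ESTABLISHED"
  expect_true("P3" %in% names(filter_pas(pas2)$geoms))
})

test_that("overlap annotates once per containing PA; nested PAs both count", {
  pas <- filter_pas(pa_fixture())
  rec <- make_records(c(0.7, 0.3, 3), c(0.7, 0.3, 3),
                      species = c("s1", "s2", "s3"))
  ov <- pa_overlap(rec, pas)
  # (0.7, 0.7) is inside both P1 and its overlapping P2
  expect_identical(sort(ov$pa_id[ov$record_id == "r001"]), c("P1", "P2"))
  expect_identical(ov$pa_id[ov$record_id == "r002"], "P1")
  expect_false("r003" %in% ov$record_id)
  # partition sanity: annotated + unannotated = all records
  expect_identical(length(unique(ov$record_id)) +
                   sum(!rec$record_id %in% ov$record_id), nrow(rec))
})

test_that("summaries match brute-force counts on a constructed fixture", {
  pas <- filter_pas(pa_fixture())
  mts <- ovd_layer(list(M1 = square(0, 0, 4)),
                   data.frame(mountain_id = "M1", area_km2 = 1))
  realms <- ovd_layer(list(A = square(0, 0, 10)),
                      data.frame(realm_id = "A"))
  rec <- make_records(c(0.7, 0.3, 0.8, 1.3), c(0.7, 0.3, 0.8, 1.3),
                      species = c("s1", "s2", "s1", "s9"),
                      class = c("bird", "mammal", "bird", "fish"))
  ov <- pa_overlap(rec, pas)
  sm <- pa_summaries(ov, pas, mts, realms, kept_records = rec)
  bc <- sm$by_category
  # brute force: category II = P1 only; records inside P1: r001, r002, r003
  ii <- bc[bc$iucn_category == "II", ]
  expect_identical(ii$n_records, 3L)
  expect_identical(ii$n_species, 2L)        # s1 counted once within II
  expect_identical(ii$bird, 1L)
  expect_identical(ii$mammal, 1L)
  # V = P2: contains r001 (0.7,0.7), r003 (0.8,0.8), r004 (1.3,1.3)
  vv <- bc[bc$iucn_category == "V", ]
  expect_identical(vv$n_records, 3L)
  expect_identical(vv$n_species, 2L)   # s1 twice in V counts once
  # area correction: the category area is the PA-mountain intersection
  expect_equal(ii$area_km2, intersection_area_km2(square(0.2, 0.2, 1),
                                                  square(0, 0, 4)),
               tolerance = 1e-9)
  expect_equal(ii$records_per_km2, 3 / ii$area_km2, tolerance = 1e-9)
  # species occurring only inside PAs: s1 (both records in PAs), s2, s9
  expect_setequal(sm$species_only_in_pas, c("s1", "s2", "s9"))
  # realm-level cumulative richness
  expect_identical(sum(sm$by_realm_category$n_species), 2L + 2L)
})

test_that("monotonicity: adding a PA never decreases a category count", {
  w <- small_world()
  rec <- assign_mountain(w$occurrences, w$mountains, check_overlap = FALSE)
  kept <- suppressWarnings(filter_native_overlap(rec, w$species))$kept
  pas <- filter_pas(w$pas)
  ids <- names(pas$geoms)
  ov_all <- pa_overlap(kept, pas)
  drop1 <- ovd_layer(pas$geoms[ids[-1]],
                     pas$data[-1, , drop = FALSE], pas$id_col)
  ov_less <- pa_overlap(kept, drop1)
  tab_all <- table(ov_all$iucn_category)
  tab_less <- table(ov_less$iucn_category)
  for (cl in names(tab_less))
    expect_gte(tab_all[cl], tab_less[cl])
})

test_that("zero mountain-portion area yields undefined (NA) densities", {
  pas <- ovd_layer(list(P9 = square(8, 8, 1)),
                   data.frame(pa_id = "P9", status = "designated",
                              iucn_category = "III"))
  mts <- ovd_layer(list(M1 = square(0, 0, 2)),
                   data.frame(mountain_id = "M1", area_km2 = 1))
  realms <- ovd_layer(list(A = square(0, 0, 10)),
                      data.frame(realm_id = "A"))
  rec <- make_records(8.5, 8.5)
  sm <- pa_summaries(pa_overlap(rec, pas), pas, mts, realms)
  expect_identical(sm$by_category$n_records, 1L)
  expect_true(is.na(sm$by_category$records_per_km2))
})
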