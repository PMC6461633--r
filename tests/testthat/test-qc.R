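# small fixture: one group, configurable PQC/blank medians per species
qc_fixture <- function(pqc_areas, blank_areas, n_pqc = 3L, n_blank = 2L,
                       group = "g1") {
  species <- names(pqc_areas)
  rows <- list()
  sp_all <- c(species, "ISTD PC")
  flags <- c(rep(FALSE, length(species)), TRUE)
  mk <- function(id, vals) tibble::tibble(
    sample_id = id, species = sp_all, panel = "PL_CE_DG",
    area = c(vals, 1000), is_istd = flags)
  for (i in seq_len(n_pqc)) {
    rows[[paste0("pqc", i)]] <- mk(paste0(group, "_PQC_", i), unname(pqc_areas))
  }
  for (i in seq_len(n_blank)) {
    rows[[paste0("bl", i)]] <- mk(paste0(group, "_BLANK_", i),
                                  unname(blank_areas))
  }
  areas <- dplyr::bind_rows(rows)
  meta <- tibble::tibble(
    sample_id = unique(areas$sample_id),
    subject_id = NA_character_, group = group, timepoint = NA_character_,
    role = rep(c("PQC", "blank"), c(n_pqc, n_blank)), sex = NA_character_)
  list(areas = areas, metadata = meta)
}

test_that("area floor and blank ratio fire on raw PQC medians", {
  fx <- qc_fixture(
    pqc_areas = c("PC 34:1" = 200, "PC 36:2" = 2000, "PC 38:4" = 2000,
                  "PC 32:0" = 5000),
    blank_areas = c("PC 34:1" = 10, "PC 36:2" = 500, "PC 38:4" = 0,
                    "PC 32:0" = 999))
  res <- area_blank_filter(fx$areas, fx$metadata, filter_config(), "g1")
  expect_equal(res$reason[res$species == "PC 34:1"], "excluded_area_floor")
  expect_equal(res$reason[res$species == "PC 36:2"], "excluded_blank_ratio")
  # zero blank median passes as ratio +Inf
  expect_true(res$pass[res$species == "PC 38:4"])
  expect_equal(res$blank_ratio[res$species == "PC 38:4"], Inf)
  expect_true(res$pass[res$species == "PC 32:0"])
  expect_error(area_blank_filter(fx$areas, fx$metadata[0, ], filter_config(),
                                 "g1"), "PQC")
})

test_that("PQC %CV is the n-1 sample CV of normalised areas", {
  expect_equal(pqc_cv(c(1, 1, 1)), 0)
  expect_equal(pqc_cv(c(0.9, 1.0, 1.1)), 100 * sd(c(0.9, 1, 1.1)) / 1)
  expect_equal(pqc_cv(c(0.9, 1.0, 1.1)), 10.0)
  expect_error(pqc_cv(1.0), "two")
  expect_true(is.na(pqc_cv(c(0, 0, 0))))
})

test_that("the CV rule is strict, cross-group, and override-aware", {
  cfg <- filter_config(override_species = c("Cer d18:1/18:0",
                                            "Hex1Cer d18:1/24:1"))
  cvs <- tibble::tibble(
    species = c("Cer d18:1/18:0", "Hex1Cer d18:1/24:1", "A", "B", "C"),
    tetracosactide = c(27.8, 30.1, 26, 25.0, NA),
    prednisolone = c(7.3, 10.9, 10, 25.0, 12))
  res <- cv_filter(cvs, cfg)
  expect_equal(res$decision[1:2], c("kept_by_override", "kept_by_override"))
  expect_equal(res$decision[res$species == "A"], "excluded_cv")
  # boundary: exactly 25% passes ("higher than" is strict)
  expect_equal(res$decision[res$species == "B"], "kept")
  expect_equal(res$decision[res$species == "C"], "excluded_missing")
})

test_that("override CVs are recorded in the report for both groups", {
  # PQC replicate vectors constructed to carry the printed CV quartet
  sim <- simulate_experiment(benign_qc_config(seed = 3))
  cfg <- filter_config(override_species = sim$truth$override_species)
  rep_qc <- qc_filter(sim$areas, sim$metadata, sim$istd_map, cfg)
  ov <- rep_qc$species[rep_qc$species$species %in% sim$truth$override_species, ]
  expect_true(all(ov$decision == "kept_by_override"))
  expect_true(all(is.finite(ov$cv_pct)))
  tet <- sort(ov$cv_pct[ov$group == "tetracosactide"])
  prd <- sort(ov$cv_pct[ov$group == "prednisolone"])
  expect_equal(tet, c(27.8, 30.1), tolerance = 0.05)
  expect_equal(prd, c(7.3, 10.9), tolerance = 0.2)
  expect_true(all(tet > 25) && all(prd < 25))
})

test_that("the cascade reports the first failing rule in documented order", {
  sim <- simulate_experiment(benign_qc_config(seed = 1))
  cfg <- filter_config(override_species = sim$truth$override_species)
  rep_qc <- qc_filter(sim$areas, sim$metadata, sim$istd_map, cfg)
  planted <- sim$truth$planted
  dec <- rep_qc$species
  # exactly one decision per species per group
  expect_equal(nrow(dec), 2L * nrow(sim$catalog))
  expect_false(any(is.na(dec$decision)))
  for (i in seq_len(nrow(planted))) {
    d <- dec$decision[dec$species == planted$species[i]]
    expected <- switch(planted$failure[i],
      area_floor = "excluded_area_floor",
      blank_ratio = "excluded_blank_ratio",
      high_cv = "excluded_cv",
      override = "kept_by_override")
    expect_equal(unique(d), expected, label = planted$species[i])
  }
  # non-planted species all kept under benign technical noise
  other <- dec$decision[!dec$species %in% planted$species]
  expect_true(all(other == "kept"))
})

test_that("raising thresholds moves the kept set monotonically", {
  sim <- simulate_experiment(benign_qc_config(seed = 2))
  kept_set <- function(cfg) {
    rep_qc <- qc_filter(sim$areas, sim$metadata, sim$istd_map, cfg)
    dec <- rep_qc$species[rep_qc$species$group == "prednisolone", ]
    dec$species[dec$decision %in% c("kept", "kept_by_override")]
  }
  base <- kept_set(filter_config())
  expect_true(all(kept_set(filter_config(area_floor = 2500)) %in% base))
  expect_true(all(kept_set(filter_config(blank_ratio_min = 50)) %in% base))
  expect_true(all(base %in% kept_set(filter_config(cv_max_pct = 99))))
})

test_that("finalisation intersects groups and enforces completeness", {
  sim <- simulate_experiment(benign_qc_config(seed = 1))
  cfg <- filter_config(override_species = sim$truth$override_species)
  rep_qc <- qc_filter(sim$areas, sim$metadata, sim$istd_map, cfg)
  q <- quantify_table(sim$areas, sim$istd_map)
  fin <- finalize_dataset(rep_qc, q$concentration, sim$metadata)
  n_excluded <- sum(sim$truth$planted$failure != "override")
  expect_equal(length(fin$final_species), nrow(sim$catalog) - n_excluded)
  expect_true(all(sim$truth$override_species %in% fin$final_species))
  expect_true(all(is.finite(fin$matrix)))

  # toy intersection semantics
  rep_toy <- rep_qc
  drop_in_pred <- fin$final_species[1]
  idx <- rep_toy$species$group == "prednisolone" &
    rep_toy$species$species == drop_in_pred
  rep_toy$species$decision[idx] <- "excluded_cv"
  fin2 <- finalize_dataset(rep_toy, q$concentration, sim$metadata)
  expect_false(drop_in_pred %in% fin2$final_species)
  expect_true(drop_in_pred %in% fin2$reporting$tetracosactide)
  expect_false(drop_in_pred %in% fin2$reporting$prednisolone)
})

test_that("panel median CVs summarise kept species per panel and group", {
  rep_fake <- structure(list(species = tibble::tibble(
    group = "g1",
    species = c("a", "b", "c", "d"),
    panel = c("P1", "P1", "P1", "P2"),
    cv_pct = c(4, 5, 6, 11),
    decision = c("kept", "kept", "kept", "kept"))),
    class = "qc_report")
  pm <- panel_median_cv(rep_fake)
  expect_equal(pm$median_pct_cv[pm$panel == "P1"], 5)
  expect_equal(pm$median_pct_cv[pm$panel == "P2"], 11)  # single species
})
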