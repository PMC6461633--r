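test_that("the catalog is deterministic, parseable and sized per class", {
  cfg <- preset_gc_study()
  built <- build_catalog(cfg)
  catalog <- built$catalog
  expect_false(anyDuplicated(catalog$species_name) > 0)
  expect_equal(nrow(catalog), 262L + sum(planted_qc_failures()$failure %in%
                 c("area_floor", "blank_ratio", "high_cv")))
  # per-class inventory mirrors the measured panels
  counts <- table(build_catalog(simulation_config())$catalog$lipid_class)
  expect_equal(unname(counts[["PI"]]), 12L)
  expect_equal(unname(counts[["Cer"]]), 16L)
  expect_equal(unname(counts[["Hex1Cer"]]), 10L)
  expect_equal(unname(counts[["PC"]]), 37L)
  expect_equal(unname(counts[["TG"]]), 31L)
  # one ISTD per class, positive concentration
  expect_equal(length(unique(built$istd_map$istd_id)), 20L)
  expect_true(all(built$istd_map$istd_conc > 0))
  # catalog does not depend on the seed
  expect_identical(catalog, build_catalog(preset_gc_study(seed = 999))$catalog)
})

test_that("simulation is a deterministic function of the configuration", {
  cfg <- preset_gc_study(seed = 42)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(preset_gc_study(seed = 42))
  expect_identical(s1$areas, s2$areas)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_experiment(preset_gc_study(seed = 43))
  expect_identical(s1$catalog, s3$catalog)
  expect_false(identical(s1$areas$area, s3$areas$area))
})

test_that("the design matches the emulated study structure", {
  sim <- simulate_experiment(preset_gc_study(seed = 1))
  md <- sim$metadata
  study <- md[md$role == "study", ]
  expect_equal(length(unique(study$subject_id[study$group == "prednisolone"])), 8L)
  expect_equal(length(unique(study$subject_id[study$group == "tetracosactide"])), 6L)
  sex <- unique(study[, c("subject_id", "group", "sex")])
  expect_equal(sum(sex$sex == "F" & sex$group == "prednisolone"), 3L)
  expect_equal(sum(sex$sex == "F" & sex$group == "tetracosactide"), 2L)
  expect_true(all(table(study$subject_id, study$timepoint) == 1L))
  expect_equal(sum(md$role == "PQC" & md$group == "prednisolone"), 8L)
  expect_equal(sum(md$role == "blank" & md$group == "tetracosactide"), 3L)
})

test_that("multiplier resolution honours species > stratum > class precedence", {
  cfg <- preset_gc_study()
  catalog <- build_catalog(cfg)$catalog
  mult <- resolve_multipliers(catalog, cfg$effect_multipliers, "tetracosactide")
  expect_equal(unname(mult[["PI 38:2"]]), 3.3)       # species beats stratum
  expect_equal(unname(mult[["PI 38:4"]]), 0.5)       # stratum (GE4)
  expect_equal(unname(mult[["PI 34:1"]]), 1.0)       # LE3 PI: no rule
  expect_equal(unname(mult[["PC 34:1"]]), 1.6)       # stratum (LE3)
  expect_equal(unname(mult[["TG 48:3"]]), 4.0)       # class-wide
  expect_equal(unname(mult[["PS 38:4"]]), 1.0)       # untouched class
  mp <- resolve_multipliers(catalog, cfg$effect_multipliers, "prednisolone")
  expect_equal(unname(mp[["Cer d18:2/18:0"]]), 2.7)
  expect_true(all(mp[catalog$species_name[catalog$lipid_class == "PI"]] == 0.45))
})

test_that("the pooled QC emulates equal-volume pooling of study samples", {
  cfg <- preset_gc_study(seed = 8)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth
  # the pool is the arithmetic mean of study-sample true concentrations
  for (g in c("prednisolone", "tetracosactide")) {
    tc <- truth$concentrations[truth$concentrations$group == g, ]
    sp <- sim$catalog$species_name[1]
    cc <- tc[tc$species == sp, ]
    expect_equal(truth$pool$pool_conc[truth$pool$group == g &
                                        truth$pool$species == sp],
                 mean(c(cc$conc_before, cc$conc_after)))
  }
  # Monte-Carlo check: measured PQC concentration matches the pool
  q <- quantify_table(sim$areas, sim$istd_map)
  pqc_ids <- sim$metadata$sample_id[sim$metadata$role == "PQC" &
                                      sim$metadata$group == "prednisolone"]
  pool_p <- truth$pool[truth$pool$group == "prednisolone", ]
  sp_big <- sim$catalog$species_name[sim$catalog$panel == "PL_CE_DG"][1:50]
  meas <- colMeans(q$concentration[pqc_ids, sp_big])
  expect_equal(unname(meas),
               pool_p$pool_conc[match(sp_big, pool_p$species)],
               tolerance = 0.1)
})

test_that("S1P d18:0 areas carry the configured M+2 cross-talk", {
  cfg <- preset_gc_study(seed = 3)
  sim <- simulate_experiment(cfg)
  cfg0 <- preset_gc_study(seed = 3)
  cfg0$s1p_m2_fraction <- 0
  sim0 <- simulate_experiment(cfg0)
  i0 <- sim$areas$species == "S1P d18:0"
  i1 <- sim$areas$species == "S1P d18:1"
  expect_equal(sim$areas$area[i0],
               sim0$areas$area[i0] + cfg$s1p_m2_fraction * sim0$areas$area[i1])
  # the pipeline's correction removes it exactly
  corrected <- correct_s1p_interference(sim$areas,
                                        fraction = cfg$s1p_m2_fraction)
  expect_equal(corrected$area[i0], sim0$areas$area[i0], tolerance = 1e-12)
})

test_that("a null configuration produces no signal", {
  sig_frac <- numeric(0)
  ratio_hits <- 0L
  n_ratio <- 0L
  for (seed in 17:19) {
    cfg <- preset_gc_study(seed = seed)
    cfg$effect_multipliers$multiplier[] <- 1
    sim <- simulate_experiment(cfg)
    expect_true(all(sim$truth$multipliers$multiplier == 1))
    q <- quantify_table(correct_s1p_interference(sim$areas), sim$istd_map)
    study <- sim$metadata[sim$metadata$role == "study", ]
    conc <- q$concentration[study$sample_id, sim$catalog$species_name]
    dt <- differential_table(conc, sim$metadata, "tetracosactide")
    sig_frac <- c(sig_frac, mean(dt$significant))
    sat <- saturation_summary(conc, sim$metadata, "tetracosactide", dt)
    ratio_hits <- ratio_hits + sum(sat$summary$p_ratio <= 0.05)
    n_ratio <- n_ratio + nrow(sat$summary)
  }
  # FDR-significant species are rare under the null
  expect_lte(mean(sig_frac), 0.05)
  # saturation-ratio changes are no more frequent than chance
  expect_lte(ratio_hits / n_ratio, 0.15)
})

test_that("configuration invariants are validated", {
  expect_error(simulation_config(groups = list(
    g1 = list(n_subjects = 1L, frac_female = 0, prefix = "A"))), "2 subjects")
  expect_error(simulation_config(effect_multipliers = tibble::tibble(
    group = "g", level = "class", target = "PC", stratum = NA,
    multiplier = -1)), "positive")
  expect_error(simulation_config(n_pqc_replicates = 1L))
  cfg <- preset_gc_study()
  expect_s3_class(cfg, "simulation_config")
  expect_true(all(cfg$technical_cv_pct >= 0))
})
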