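# --- deterministic species catalog -----------------------------------------

.panel_of_class <- c(
  Cer = "SPHINGO", Hex1Cer = "SPHINGO", Hex2Cer = "SPHINGO", GM3 = "SPHINGO",
  SM = "SPHINGO", S1P = "S1P",
  LPC = "PL_CE_DG", `LPC-O` = "PL_CE_DG", PC = "PL_CE_DG", `PC-O` = "PL_CE_DG",
  `PC-P` = "PL_CE_DG", LPE = "PL_CE_DG", PE = "PL_CE_DG", `PE-O` = "PL_CE_DG",
  `PE-P` = "PL_CE_DG", PI = "PL_CE_DG", PS = "PL_CE_DG", DG = "PL_CE_DG",
  CE = "PL_CE_DG", TG = "TG")

# typical relative molar abundance scale per class (umol/L); order-of-magnitude
# plasma values, irrelevant to the ratio/CV-based analyses
.class_base_conc <- c(
  Cer = 1, Hex1Cer = 0.4, Hex2Cer = 0.15, GM3 = 0.3, SM = 40, S1P = 0.3,
  LPC = 30, `LPC-O` = 0.8, PC = 150, `PC-O` = 4, `PC-P` = 2, LPE = 2,
  PE = 8, `PE-O` = 0.5, `PE-P` = 1.5, PI = 10, PS = 0.3, DG = 3, TG = 40,
  CE = 120)

.base_species_names <- function() {
  sph <- function(cls, base, acyls) paste0(cls, " ", base, "/", acyls)
  c(
    sph("Cer", "d18:1", c("16:0", "18:0", "18:1", "20:0", "22:0", "23:0",
                          "24:0", "24:1", "26:0", "26:1")),
    sph("Cer", "d18:2", c("16:0", "18:0", "22:0", "24:0")),
    sph("Cer", "d16:1", c("22:0", "24:0")),
    sph("Hex1Cer", "d18:1", c("16:0", "18:0", "22:0", "23:0", "24:0", "24:1",
                              "26:1")),
    sph("Hex1Cer", "d18:2", c("16:0", "24:0", "24:1")),
    sph("Hex2Cer", "d18:1", c("16:0", "18:0", "22:0", "23:0", "24:0", "24:1")),
    sph("Hex2Cer", "d18:2", c("16:0", "18:0", "24:0", "24:1")),
    sph("GM3", "d18:1", c("16:0", "18:0", "22:0", "24:0", "24:1")),
    sph("GM3", "d18:2", c("16:0", "18:0", "24:1")),
    paste("SM", c("30:1", "32:0", "32:1", "32:2", "33:1", "34:0", "34:1",
                  "34:2", "35:1", "36:0", "36:1", "36:2", "36:3", "38:1",
                  "38:2", "39:1", "40:1", "40:2", "41:1", "41:2", "42:1",
                  "42:2", "42:3", "43:1")),
    paste("S1P", c("d16:1", "d17:1", "d18:0", "d18:1", "d18:2", "d20:1")),
    paste("LPC", c("14:0", "15:0", "16:0", "16:1", "17:0", "17:1", "18:0",
                   "18:1", "18:2", "18:3", "19:0", "20:0", "20:1", "20:3",
                   "20:4", "20:5", "22:4", "22:5", "22:6", "24:0", "26:0")),
    paste("LPC-O", c("16:0", "16:1", "17:0", "18:0", "18:1")),
    paste("LPE", c("16:0", "18:0", "18:1", "18:2", "20:4")),
    paste("PC", c("30:0", "32:0", "32:1", "32:2", "33:1", "34:0", "34:1",
                  "34:2", "34:3", "34:4", "35:1", "35:2", "36:1", "36:2",
                  "36:3", "36:4", "36:5", "36:6", "37:2", "37:4", "38:2",
                  "38:3", "38:4", "38:5", "38:6", "39:4", "40:4", "40:5",
                  "40:6", "40:7", "40:8", "41:6", "42:4", "42:5", "42:6",
                  "42:7", "44:8")),
    paste("PC-O", c("32:0", "32:1", "34:0", "34:1", "34:2", "34:3", "36:1",
                    "36:2", "36:3", "36:4", "36:5", "38:4", "38:5", "40:5",
                    "40:7")),
    paste("PC-P", c("32:0", "32:1", "34:1", "34:2", "36:1", "36:2", "36:4",
                    "38:4", "38:5", "38:6", "40:5", "40:6")),
    paste("PE", c("32:1", "34:1", "34:2", "36:1", "36:2", "36:3", "36:4",
                  "38:3", "38:4", "38:5", "38:6", "40:5", "40:6")),
    paste("PE-O", c("16:0/20:4", "18:1/20:3", "18:1/20:4")),
    paste("PE-P", c("16:0/18:2", "16:0/20:4", "16:0/22:6", "18:0/18:1",
                    "18:0/18:2", "18:0/20:4", "18:0/22:6", "18:1/18:2",
                    "18:1/20:4")),
    paste("PI", c("32:0", "32:1", "34:1", "34:2", "36:1", "36:2", "36:3",
                  "36:4", "38:2", "38:3", "38:4", "38:5")),
    paste("PS", c("36:1", "38:4")),
    paste("DG", c("16:0_18:1", "16:0_18:2", "18:0_18:1", "18:0_18:2",
                  "18:1_18:1", "18:1_18:2")),
    paste("TG", c("44:1", "46:1", "46:2", "48:1", "48:2", "48:3", "50:1",
                  "50:2", "50:3", "50:4", "51:2", "51:3", "52:2", "52:3",
                  "52:4", "52:5", "53:2", "53:3", "54:3", "54:4", "54:5",
                  "54:6", "55:3", "56:5", "56:6", "56:7", "58:6", "58:7",
                  "58:8", "60:8", "60:9")),
    paste("CE", c("14:0", "15:0", "16:0", "16:1", "17:0", "17:1", "18:0",
                  "18:1", "18:2", "18:3", "20:3", "20:4", "20:5", "22:4",
                  "22:5", "22:6", "24:4"))
  )
}

#' Default planted QC failures
#'
#' The species planted into the default study preset to exercise every branch
#' of the QC cascade: three below the area floor, two with blank
#' contamination, four with inflated pooled-QC variability, and two
#' override-retained species whose %CV exceeds the cutoff in the
#' tetracosactide group only (the cross-group comparability exception).
#'
#' @return Tibble: `species`, `failure` (one of `area_floor`, `blank_ratio`,
#'   `high_cv`, `override`).
#' @export
planted_qc_failures <- function() {
  tibble::tibble(
    species = c("PE 40:7", "TG 62:10", "Hex2Cer d18:1/26:0",
                "LPC 28:0", "CE 26:0",
                "SM 43:2", "PC 44:10", "TG 61:3", "Cer d16:1/26:0",
                "Cer d18:1/18:0", "Hex1Cer d18:1/24:1"),
    failure = c(rep("area_floor", 3), rep("blank_ratio", 2),
                rep("high_cv", 4), rep("override", 2))
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study generator. The defaults
#' encode the emulated two-arm paired design: 8 prednisolone and 6
#' tetracosactide dogs (about one-third female), pooled PQC replicates and
#' blanks per group, four analytical panels with panel-specific technical
#' %CVs on the order of the reported panel precisions, lognormal biological
#' spread across subjects, low blank background, and M+2 isotope cross-talk
#' from S1P d18:1 into S1P d18:0 that the pipeline must remove.
#'
#' @param seed Integer seed; the full output is a deterministic function of
#'   the configuration (identical config, identical bytes).
#' @param groups Named list per group: `n_subjects`, `frac_female`,
#'   `prefix` (subject-id prefix).
#' @param effect_multipliers Tibble (`group`, `level` in
#'   `"class"`/`"class_stratum"`/`"species"`, `target`, `stratum`,
#'   `multiplier`) of true after/before effects; precedence
#'   species > class_stratum > class > 1.
#' @param planted Tibble (`species`, `failure`) of planted QC failures; the
#'   species are appended to the catalog (see [planted_qc_failures()]).
#' @param pqc_cv_overrides Tibble (`group`, `species`, `cv_pct`): these
#'   species' PQC replicates follow a deterministic mean-zero unit-sd
#'   pattern scaled so the realized sample %CV equals `cv_pct` (up to the
#'   small ISTD noise), which pins the CV-filter behaviour of selected
#'   species regardless of seed.
#' @param technical_cv_pct Named per-panel technical %CV of analyte areas.
#' @param biological_cv_pct Between-subject lognormal %CV of baselines.
#' @param istd_area_mean Named per-panel mean ISTD peak area.
#' @param istd_cv_pct Technical %CV of ISTD areas.
#' @param injection_cv_pct Per-sample injection scale %CV (shared by all
#'   areas of a sample; cancels under ISTD normalisation).
#' @param blank_fraction Blank signal as a fraction of the pooled-QC signal.
#' @param n_pqc_replicates PQC injection replicates per group (>= 2).
#' @param n_blanks Blank samples per group (>= 1).
#' @param s1p_m2_fraction M+2 cross-talk fraction added to S1P d18:0.
#' @param istd_conc Spiked ISTD concentration (umol/L) for every class.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    groups = list(
      prednisolone = list(n_subjects = 8L, frac_female = 3 / 8, prefix = "P"),
      tetracosactide = list(n_subjects = 6L, frac_female = 2 / 6, prefix = "T")),
    effect_multipliers = tibble::tibble(group = character(0),
                                        level = character(0),
                                        target = character(0),
                                        stratum = character(0),
                                        multiplier = numeric(0)),
    planted = planted_qc_failures()[0, ],
    pqc_cv_overrides = tibble::tibble(group = character(0),
                                      species = character(0),
                                      cv_pct = numeric(0)),
    technical_cv_pct = c(PL_CE_DG = 5, SPHINGO = 11, S1P = 9, TG = 18),
    biological_cv_pct = 40,
    istd_area_mean = c(PL_CE_DG = 5e4, SPHINGO = 4e4, S1P = 3e4, TG = 6e4),
    istd_cv_pct = 2,
    injection_cv_pct = 5,
    blank_fraction = 0.01,
    n_pqc_replicates = 8L,
    n_blanks = 3L,
    s1p_m2_fraction = isotope_m2_fraction(18L),
    istd_conc = 1.0) {
  stopifnot(all(technical_cv_pct >= 0), biological_cv_pct >= 0,
            istd_cv_pct >= 0, injection_cv_pct >= 0,
            blank_fraction >= 0, n_pqc_replicates >= 2L, n_blanks >= 1L,
            s1p_m2_fraction >= 0, istd_conc > 0)
  if (nrow(effect_multipliers) > 0 && any(effect_multipliers$multiplier <= 0)) {
    stop("effect multipliers must be positive", call. = FALSE)
  }
  for (g in names(groups)) {
    if (groups[[g]]$n_subjects < 2L) {
      stop("group '", g, "' needs at least 2 subjects", call. = FALSE)
    }
  }
  structure(list(
    seed = as.integer(seed), groups = groups,
    effect_multipliers = effect_multipliers, planted = planted,
    pqc_cv_overrides = pqc_cv_overrides,
    technical_cv_pct = technical_cv_pct,
    biological_cv_pct = biological_cv_pct,
    istd_area_mean = istd_area_mean, istd_cv_pct = istd_cv_pct,
    injection_cv_pct = injection_cv_pct, blank_fraction = blank_fraction,
    n_pqc_replicates = as.integer(n_pqc_replicates),
    n_blanks = as.integer(n_blanks),
    s1p_m2_fraction = s1p_m2_fraction, istd_conc = istd_conc),
    class = "simulation_config")
}

#' Build the deterministic species catalog and ISTD map
#'
#' Enumerates the 20-class species catalog (262 species emulating the
#' measured panels, every name shorthand-parseable and unique) plus any
#' planted-failure species from the configuration, assigns each class one
#' internal standard on its panel, and attaches per-species baseline
#' concentrations. The catalog does not depend on the seed.
#'
#' @param config A [simulation_config()].
#' @return List: `catalog` (tibble `species_name`, `panel`, `istd_id`,
#'   `lipid_class`, `total_double_bonds`, `base_conc`), `istd_map`
#'   (`species`, `istd_id`, `istd_conc`).
#' @export
build_catalog <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  names_all <- .base_species_names()
  extra <- setdiff(config$planted$species, names_all)
  names_all <- c(names_all, extra)
  if (anyDuplicated(names_all)) {
    stop("duplicate generated species names", call. = FALSE)
  }
  parsed <- parse_lipid_names(names_all)
  cls <- parsed$lipid_class
  panel <- unname(.panel_of_class[cls])

  # deterministic within-class abundance spread (0.3x to 3x the class base)
  base_conc <- numeric(length(names_all))
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    base_conc[idx] <- .class_base_conc[[cl]] *
      exp(seq(log(0.3), log(3), length.out = length(idx)))
  }
  # planted area-floor species sit far below the floor in raw area terms
  af <- names_all %in%
    config$planted$species[config$planted$failure == "area_floor"]
  base_conc[af] <- 55 / config$istd_area_mean[panel[af]] * config$istd_conc

  catalog <- tibble::tibble(
    species_name = names_all,
    panel = panel,
    istd_id = paste("ISTD", cls),
    lipid_class = cls,
    total_carbons = parsed$total_carbons,
    total_double_bonds = parsed$total_double_bonds,
    base_conc = base_conc
  )
  istd_map <- tibble::tibble(
    species = catalog$species_name,
    istd_id = catalog$istd_id,
    istd_conc = config$istd_conc
  )
  list(catalog = catalog, istd_map = istd_map)
}

# multiplicative lognormal noise with unit mean
.ln_noise <- function(n, cv_pct) {
  if (length(cv_pct) == 1L) cv_pct <- rep(cv_pct, n)
  sigma <- sqrt(log(1 + (cv_pct / 100)^2))
  exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
}

#' Resolve true effect multipliers per species
#'
#' Applies the configuration's effect rules to a catalog for one group, with
#' precedence species-specific > class-and-stratum > class-wide > 1.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param effects `effect_multipliers` tibble (see [simulation_config()]).
#' @param group Group label.
#' @return Named numeric vector of multipliers, one per catalog species.
#' @export
resolve_multipliers <- function(catalog, effects, group) {
  mult <- rep(1, nrow(catalog))
  names(mult) <- catalog$species_name
  ef <- effects[effects$group == group, , drop = FALSE]
  strata <- saturation_group(catalog$total_double_bonds)
  for (lvl in c("class", "class_stratum", "species")) {
    sub <- ef[ef$level == lvl, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      hit <- switch(lvl,
        class = catalog$lipid_class == sub$target[i],
        class_stratum = catalog$lipid_class == sub$target[i] &
          !is.na(strata) & strata == sub$stratum[i],
        species = catalog$species_name == sub$target[i])
      mult[hit] <- sub$multiplier[i]
    }
  }
  mult
}

#' Simulate a complete synthetic experiment
#'
#' Generates the peak-area table, sample metadata, ISTD map and ground truth
#' for the configured two-arm paired study. Per subject and species, the
#' before-treatment concentration is lognormal around the catalog baseline
#' (between-subject biological %CV); the after concentration multiplies in
#' the group's true effect. Areas are concentrations scaled by the panel's
#' ISTD response, a shared per-sample injection factor, and lognormal
#' technical noise. Pooled-QC samples are generated from the equal-volume
#' pool (arithmetic mean of the group's study-sample concentrations, before
#' technical noise), blanks carry `blank_fraction` of the pooled signal, and
#' S1P d18:0 areas receive the configured M+2 cross-talk from S1P d18:1, so
#' the pipeline has to subtract it back out.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_experiment`: `areas` (long peak-area
#'   tibble: `sample_id`, `species`, `panel`, `area`, `is_istd`), `metadata`
#'   (`sample_id`, `subject_id`, `group`, `timepoint`, `role`, `sex`),
#'   `istd_map`, `catalog`, and `truth` (true multipliers, per-subject true
#'   concentrations, pool concentrations, planted failures, config echo).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  built <- build_catalog(config)
  catalog <- built$catalog
  set.seed(config$seed)

  n_sp <- nrow(catalog)
  blank_frac <- rep(config$blank_fraction, n_sp)
  blank_frac[catalog$species_name %in%
               config$planted$species[config$planted$failure == "blank_ratio"]] <- 0.5
  tech_cv <- unname(config$technical_cv_pct[catalog$panel])
  high_cv_sp <- config$planted$species[config$planted$failure == "high_cv"]

  areas_list <- list()
  meta_list <- list()
  truth_mult <- list()
  truth_conc <- list()
  truth_pool <- list()

  istd_ids <- unique(catalog$istd_id)
  istd_panel <- catalog$panel[match(istd_ids, catalog$istd_id)]
  istd_mean <- unname(config$istd_area_mean[istd_panel])

  emit_sample <- function(sample_id, conc, tech_cv_sample,
                          det_idx = integer(0), det_factor = numeric(0)) {
    inj <- .ln_noise(1L, config$injection_cv_pct)
    analyte_area <- conc / config$istd_conc *
      unname(config$istd_area_mean[catalog$panel]) * inj *
      .ln_noise(n_sp, tech_cv_sample)
    if (length(det_idx) > 0L) {
      analyte_area[det_idx] <- conc[det_idx] / config$istd_conc *
        unname(config$istd_area_mean[catalog$panel[det_idx]]) * inj * det_factor
    }
    istd_area <- istd_mean * inj * .ln_noise(length(istd_ids), config$istd_cv_pct)
    tibble::tibble(
      sample_id = sample_id,
      species = c(catalog$species_name, istd_ids),
      panel = c(catalog$panel, istd_panel),
      area = c(analyte_area, istd_area),
      is_istd = c(rep(FALSE, n_sp), rep(TRUE, length(istd_ids)))
    )
  }

  for (g in names(config$groups)) {
    gs <- config$groups[[g]]
    subjects <- paste0(gs$prefix, seq_len(gs$n_subjects))
    n_f <- round(gs$frac_female * gs$n_subjects)
    sex <- c(rep("M", gs$n_subjects - n_f), rep("F", n_f))
    mult <- resolve_multipliers(catalog, config$effect_multipliers, g)

    pqc_cv <- tech_cv
    pqc_cv[catalog$species_name %in% high_cv_sp] <- 150
    # species with a configured PQC %CV get a deterministic mean-zero,
    # unit-sd replicate pattern scaled to that CV, so the realized sample CV
    # is the configured one (up to the small ISTD noise)
    ov <- config$pqc_cv_overrides[config$pqc_cv_overrides$group == g, ,
                                  drop = FALSE]
    ov_idx <- match(ov$species, catalog$species_name)
    if (anyNA(ov_idx)) {
      stop("pqc_cv_overrides species not in catalog: ",
           paste(ov$species[is.na(ov_idx)], collapse = ", "), call. = FALSE)
    }
    zpat <- if (config$n_pqc_replicates > 1L)
      as.numeric(scale(seq_len(config$n_pqc_replicates))) else 0

    conc_before <- sapply(subjects, function(s)
      catalog$base_conc * .ln_noise(n_sp, config$biological_cv_pct))
    conc_after <- conc_before * mult

    for (i in seq_along(subjects)) {
      s <- subjects[i]
      areas_list[[paste0(s, "_before")]] <-
        emit_sample(paste0(s, "_before"), conc_before[, i], tech_cv)
      areas_list[[paste0(s, "_after")]] <-
        emit_sample(paste0(s, "_after"), conc_after[, i], tech_cv)
      meta_list[[length(meta_list) + 1L]] <- tibble::tibble(
        sample_id = paste0(s, c("_before", "_after")),
        subject_id = s, group = g, timepoint = c("before", "after"),
        role = "study", sex = sex[i])
    }

    pool <- rowMeans(cbind(conc_before, conc_after))
    truth_pool[[g]] <- tibble::tibble(group = g,
                                      species = catalog$species_name,
                                      pool_conc = pool)
    for (r in seq_len(config$n_pqc_replicates)) {
      id <- sprintf("%s_PQC_%d", g, r)
      areas_list[[id]] <- emit_sample(
        id, pool, pqc_cv, det_idx = ov_idx,
        det_factor = pmax(1 + (ov$cv_pct / 100) * zpat[r], 1e-6))
      meta_list[[length(meta_list) + 1L]] <- tibble::tibble(
        sample_id = id, subject_id = NA_character_, group = g,
        timepoint = NA_character_, role = "PQC", sex = NA_character_)
    }
    for (r in seq_len(config$n_blanks)) {
      id <- sprintf("%s_BLANK_%d", g, r)
      areas_list[[id]] <- emit_sample(id, pool * blank_frac, tech_cv)
      meta_list[[length(meta_list) + 1L]] <- tibble::tibble(
        sample_id = id, subject_id = NA_character_, group = g,
        timepoint = NA_character_, role = "blank", sex = NA_character_)
    }

    truth_mult[[g]] <- tibble::tibble(group = g,
                                      species = catalog$species_name,
                                      multiplier = unname(mult))
    truth_conc[[g]] <- dplyr::bind_rows(lapply(seq_along(subjects), function(i)
      tibble::tibble(group = g, subject_id = subjects[i],
                     species = catalog$species_name,
                     conc_before = conc_before[, i],
                     conc_after = conc_after[, i])))
  }

  areas <- dplyr::bind_rows(areas_list)
  # M+2 isotope cross-talk: S1P d18:1 leaks into the S1P d18:0 channel
  if (config$s1p_m2_fraction > 0 &&
      all(c("S1P d18:0", "S1P d18:1") %in% catalog$species_name)) {
    key <- split(seq_len(nrow(areas)), areas$species)
    i0 <- key[["S1P d18:0"]]
    i1 <- key[["S1P d18:1"]]
    stopifnot(identical(areas$sample_id[i0], areas$sample_id[i1]))
    areas$area[i0] <- areas$area[i0] + config$s1p_m2_fraction * areas$area[i1]
  }

  structure(list(
    areas = areas,
    metadata = dplyr::bind_rows(meta_list),
    istd_map = built$istd_map,
    catalog = catalog,
    truth = list(
      multipliers = dplyr::bind_rows(truth_mult),
      concentrations = dplyr::bind_rows(truth_conc),
      pool = dplyr::bind_rows(truth_pool),
      planted = config$planted,
      override_species = config$planted$species[
        config$planted$failure == "override"],
      config = config)
  ), class = "synthetic_experiment")
}

#' Study-like simulation preset
#'
#' A [simulation_config()] encoding the headline effect structure of the
#' glucocorticoid study: monohexosylceramides up in both arms; PI, and most
#' S1P, changed after short-term prednisolone (PI down about twofold, S1P up
#' about 1.5-fold, Cer d18:2/18:0 up 2.7-fold); and after long-term
#' tetracosactide, ether/plasmalogen PC and LPC-O down, TG strongly up,
#' polyunsaturated (>= 4 double bond) PC/PE/PI down with their saturated
#' counterparts up, S1P d16:1 down, and Cer d18:1/18:0 up 3.3-fold. Planted
#' QC failures and the two override-retained sphingolipids (elevated pooled
#' QC variability in the tetracosactide arm only) are included so the filter
#' cascade is fully exercised.
#'
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
preset_gc_study <- function(seed = 1L) {
  ef <- function(group, level, target, multiplier, stratum = NA_character_) {
    tibble::tibble(group = group, level = level, target = target,
                   stratum = stratum, multiplier = multiplier)
  }
  effects <- dplyr::bind_rows(
    # short-term prednisolone
    ef("prednisolone", "class", "Hex1Cer", 1.9),
    ef("prednisolone", "class", "PI", 0.45),
    ef("prednisolone", "class", "S1P", 1.5),
    ef("prednisolone", "species", "Cer d18:2/18:0", 2.7),
    ef("prednisolone", "species", "GM3 d18:2/18:0", 0.63),
    ef("prednisolone", "species", "LPC 19:0", 0.45),
    ef("prednisolone", "species", "LPC 20:5", 4.5),
    ef("prednisolone", "species", "PE 34:1", 1.6),
    ef("prednisolone", "species", "SM 32:2", 1.5),
    ef("prednisolone", "species", "CE 24:4", 2.8),
    ef("prednisolone", "species", "TG 48:3", 0.55),
    # long-term tetracosactide
    ef("tetracosactide", "class", "Hex1Cer", 2.2),
    ef("tetracosactide", "class", "PC-O", 0.45),
    ef("tetracosactide", "class", "PC-P", 0.45),
    ef("tetracosactide", "class", "LPC-O", 0.5),
    ef("tetracosactide", "class", "TG", 4.0),
    ef("tetracosactide", "class_stratum", "PC", 0.55, "GE4"),
    ef("tetracosactide", "class_stratum", "PC", 1.6, "LE3"),
    ef("tetracosactide", "class_stratum", "PE", 0.6, "GE4"),
    ef("tetracosactide", "class_stratum", "PE", 1.5, "LE3"),
    ef("tetracosactide", "class_stratum", "PI", 0.5, "GE4"),
    ef("tetracosactide", "species", "PI 38:2", 3.3),
    ef("tetracosactide", "species", "Cer d18:1/18:0", 3.3),
    ef("tetracosactide", "species", "S1P d16:1", 0.48),
    ef("tetracosactide", "species", "GM3 d18:1/18:0", 0.45),
    ef("tetracosactide", "species", "GM3 d18:2/18:0", 0.26),
    ef("tetracosactide", "species", "SM 34:0", 1.7),
    ef("tetracosactide", "species", "SM 36:1", 2.2),
    ef("tetracosactide", "species", "LPE 18:2", 1.6),
    ef("tetracosactide", "species", "LPC 20:3", 2.4),
    ef("tetracosactide", "species", "PE-O 18:1/20:3", 0.42),
    ef("tetracosactide", "species", "PE-P 18:0/18:2", 2.1),
    ef("tetracosactide", "species", "DG 18:0_18:2", 4.4),
    ef("tetracosactide", "species", "CE 20:4", 0.42),
    ef("tetracosactide", "species", "CE 22:4", 0.40),
    ef("tetracosactide", "species", "CE 22:5", 0.40)
  )
  planted <- planted_qc_failures()
  overrides <- planted$species[planted$failure == "override"]
  cv_over <- dplyr::bind_rows(
    tibble::tibble(group = "tetracosactide", species = overrides,
                   cv_pct = c(27.8, 30.1)),
    tibble::tibble(group = "prednisolone", species = overrides,
                   cv_pct = c(7.3, 10.9))
  )
  simulation_config(seed = seed, effect_multipliers = effects,
                    planted = planted, pqc_cv_overrides = cv_over)
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment>", nrow(x$catalog), "species,",
      length(unique(x$metadata$sample_id)), "samples,",
      nrow(x$areas), "peak-area rows\n")
  invisible(x)
}
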