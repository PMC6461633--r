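#' Species-exclusion filter configuration
#'
#' Thresholds of the pooled-QC exclusion cascade: a species is dropped when
#' its median raw peak area in the group's pooled QC (PQC) samples falls
#' below `area_floor`, when that median is less than `blank_ratio_min` times
#' the median blank area, or when the %CV of its ISTD-normalised area across
#' PQC replicates exceeds `cv_max_pct` in any group. Species listed in
#' `override_species` survive the CV rule (decision `kept_by_override`) so
#' both treatment groups stay comparable on them.
#'
#' @param area_floor Minimum median PQC raw area. Default 250.
#' @param blank_ratio_min Minimum PQC/blank median-area ratio. Default 5.
#' @param cv_max_pct Maximum PQC %CV (strictly greater fails). Default 25.
#' @param override_species Character vector of species exempt from the CV rule.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(area_floor = 250, blank_ratio_min = 5,
                          cv_max_pct = 25, override_species = character(0)) {
  if (area_floor <= 0 || blank_ratio_min <= 0 || cv_max_pct <= 0) {
    stop("all filter thresholds must be positive", call. = FALSE)
  }
  structure(list(area_floor = area_floor, blank_ratio_min = blank_ratio_min,
                 cv_max_pct = cv_max_pct,
                 override_species = as.character(override_species)),
            class = "filter_config")
}

#' Coefficient of variation of PQC replicates
#'
#' `100 * sd / mean` with the n-1 standard deviation, over the normalised
#' areas of one species in a group's PQC replicates.
#'
#' @param normalized_areas Numeric vector, at least two replicates.
#' @return %CV, or `NA` when the mean is not positive (the species is then
#'   flagged `excluded_missing` downstream).
#' @export
pqc_cv <- function(normalized_areas) {
  x <- normalized_areas[!is.na(normalized_areas)]
  if (length(x) < 2L) {
    stop("at least two PQC replicates are required for a CV", call. = FALSE)
  }
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Area-floor and blank-ratio filter for one group
#'
#' Evaluates the two raw-area exclusion rules on a group's PQC and blank
#' samples: median PQC area below the floor, or less than `blank_ratio_min`
#' times the median blank area. A blank median of zero passes the ratio rule
#' (ratio `Inf`): absent background cannot justify exclusion. Both rules use
#' raw (not normalised) areas.
#'
#' @param areas Peak-area table (`sample_id`, `species`, `area`, `is_istd`).
#' @param metadata Sample metadata with `sample_id`, `group`, `role`
#'   (`"study"`, `"PQC"`, `"blank"`).
#' @param config A [filter_config()].
#' @param group Group label to evaluate.
#' @return Tibble per species: `median_pqc_area`, `median_blank_area`,
#'   `blank_ratio`, `pass`, `reason` (`NA` when passing).
#' @export
area_blank_filter <- function(areas, metadata, config, group) {
  stopifnot(inherits(config, "filter_config"))
  pqc_ids <- metadata$sample_id[metadata$role == "PQC" & metadata$group == group]
  blank_ids <- metadata$sample_id[metadata$role == "blank" & metadata$group == group]
  if (length(pqc_ids) == 0L) {
    stop("group '", group, "' has no PQC samples", call. = FALSE)
  }
  if (length(blank_ids) == 0L) {
    stop("group '", group, "' has no blank samples", call. = FALSE)
  }
  an <- areas[!areas$is_istd, , drop = FALSE]
  species <- unique(an$species)
  med <- function(ids) {
    sub <- an[an$sample_id %in% ids, , drop = FALSE]
    out <- tapply(sub$area, factor(sub$species, levels = species), stats::median)
    as.numeric(out)
  }
  med_pqc <- med(pqc_ids)
  med_blank <- med(blank_ids)
  med_blank[is.na(med_blank)] <- 0
  ratio <- ifelse(med_blank == 0, Inf, med_pqc / med_blank)
  reason <- rep(NA_character_, length(species))
  reason[!is.na(med_pqc) & med_pqc < config$area_floor] <- "excluded_area_floor"
  reason[is.na(reason) & !is.na(med_pqc) &
           ratio < config$blank_ratio_min] <- "excluded_blank_ratio"
  reason[is.na(med_pqc)] <- "excluded_missing"
  tibble::tibble(
    species = species,
    median_pqc_area = med_pqc,
    median_blank_area = med_blank,
    blank_ratio = ratio,
    pass = is.na(reason),
    reason = reason
  )
}

#' CV filter across groups
#'
#' A species is excluded when its PQC %CV exceeds the threshold (strictly) in
#' at least one group, unless it is on the override list, in which case it is
#' kept with decision `kept_by_override` and both CVs remain on record.
#' Species with an unavailable CV in any group are `excluded_missing`.
#'
#' @param cv_by_group Tibble with a `species` column and one numeric %CV
#'   column per group.
#' @param config A [filter_config()].
#' @return Tibble: `species`, `max_cv_pct`, `decision` (one of `kept`,
#'   `kept_by_override`, `excluded_cv`, `excluded_missing`).
#' @export
cv_filter <- function(cv_by_group, config) {
  stopifnot(inherits(config, "filter_config"), "species" %in% names(cv_by_group))
  cvs <- as.matrix(cv_by_group[, setdiff(names(cv_by_group), "species"), drop = FALSE])
  any_na <- apply(cvs, 1L, function(r) any(is.na(r)))
  max_cv <- suppressWarnings(apply(cvs, 1L, max, na.rm = TRUE))
  max_cv[!is.finite(max_cv)] <- NA_real_
  over <- !any_na & max_cv > config$cv_max_pct
  decision <- rep("kept", nrow(cv_by_group))
  decision[over] <- ifelse(cv_by_group$species[over] %in% config$override_species,
                           "kept_by_override", "excluded_cv")
  decision[any_na] <- "excluded_missing"
  tibble::tibble(species = cv_by_group$species, max_cv_pct = max_cv,
                 decision = decision)
}

#' Run the full QC exclusion cascade
#'
#' Applies, per experimental group, the area-floor, blank-ratio and PQC-%CV
#' rules to every analyte species and records exactly one decision per
#' species and group, with the first failing rule as the reason (documented
#' order: area floor, then blank ratio, then CV; the kept/excluded outcome is
#' order-independent). Normalised areas for the CV rule are computed from the
#' group's PQC samples against their own ISTD areas.
#'
#' @param areas Peak-area table (`sample_id`, `species`, `panel`, `area`,
#'   `is_istd`), isotope-corrected.
#' @param metadata Sample metadata (`sample_id`, `group`, `role`).
#' @param istd_map ISTD assignment (`species`, `istd_id`, `istd_conc`).
#' @param config A [filter_config()].
#' @return An object of class `qc_report`: list with `species` (per group and
#'   species: medians, blank ratio, `cv_pct`, `decision`, `reason`),
#'   `panel_medians` (per panel and group median %CV over kept species),
#'   `cv_by_group` (wide %CV table) and `config`.
#' @export
qc_filter <- function(areas, metadata, istd_map, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  groups <- unique(metadata$group[metadata$role == "study"])
  an <- areas[!areas$is_istd, , drop = FALSE]
  species <- unique(an$species)
  panel <- an$panel[match(species, an$species)]

  per_group <- lapply(groups, function(g) {
    ab <- area_blank_filter(areas, metadata, config, g)
    pqc_ids <- metadata$sample_id[metadata$role == "PQC" & metadata$group == g]
    qpqc <- quantify_table(areas[areas$sample_id %in% pqc_ids, , drop = FALSE],
                           istd_map)
    cv <- vapply(species, function(sp) {
      if (!sp %in% colnames(qpqc$normalized)) return(NA_real_)
      v <- qpqc$normalized[, sp]
      if (sum(!is.na(v)) < 2L) return(NA_real_)
      pqc_cv(v)
    }, numeric(1))
    tibble::tibble(
      group = g,
      species = species,
      panel = panel,
      median_pqc_area = ab$median_pqc_area[match(species, ab$species)],
      median_blank_area = ab$median_blank_area[match(species, ab$species)],
      blank_ratio = ab$blank_ratio[match(species, ab$species)],
      area_blank_reason = ab$reason[match(species, ab$species)],
      cv_pct = unname(cv)
    )
  })
  long <- dplyr::bind_rows(per_group)

  cv_wide <- tidyr::pivot_wider(long[, c("species", "group", "cv_pct")],
                                names_from = "group", values_from = "cv_pct")
  cvd <- cv_filter(cv_wide, config)

  # first-failing reason in documented order: area floor -> blank -> CV
  cv_dec <- cvd$decision[match(long$species, cvd$species)]
  decision <- ifelse(!is.na(long$area_blank_reason), long$area_blank_reason,
                     cv_dec)
  reason <- dplyr::case_when(
    decision == "excluded_area_floor" ~ sprintf(
      "median PQC area %.1f below floor %.0f", long$median_pqc_area,
      config$area_floor),
    decision == "excluded_blank_ratio" ~ sprintf(
      "PQC/blank ratio %.2f below %.1f", long$blank_ratio,
      config$blank_ratio_min),
    decision == "excluded_cv" ~ sprintf(
      "PQC CV %.1f%% above %.1f%% in at least one group",
      cvd$max_cv_pct[match(long$species, cvd$species)], config$cv_max_pct),
    decision == "kept_by_override" ~ "CV above threshold but species on override list",
    decision == "excluded_missing" ~ "species not quantifiable in PQC samples",
    TRUE ~ "passed all QC rules"
  )
  long$decision <- decision
  long$reason <- reason
  long$area_blank_reason <- NULL

  report <- structure(list(species = long, cv_by_group = cv_wide,
                           config = config),
                      class = "qc_report")
  report$panel_medians <- panel_median_cv(report)
  report
}

#' Per-panel median %CV of kept species
#'
#' Median of the per-species PQC %CVs over the species kept in each group
#' (including override retentions), summarised per analytical panel, the
#' standard figure of merit for each panel's precision.
#'
#' @param report A `qc_report` from [qc_filter()].
#' @return Tibble: `panel`, `group`, `n_kept`, `median_pct_cv`.
#' @export
panel_median_cv <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  kept <- report$species[report$species$decision %in%
                           c("kept", "kept_by_override"), , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no kept species; panel medians omitted", call. = FALSE)
    return(tibble::tibble(panel = character(0), group = character(0),
                          n_kept = integer(0), median_pct_cv = numeric(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(kept, .data$panel, .data$group),
    n_kept = dplyr::n(),
    median_pct_cv = stats::median(.data$cv_pct),
    .groups = "drop")
  empty <- setdiff(unique(report$species$panel), unique(out$panel))
  if (length(empty) > 0L) {
    warning("panel(s) without kept species omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}

#' Finalise the cross-group dataset
#'
#' Intersects the per-group QC decisions: the final species set contains the
#' species kept in every group that also have a finite concentration in every
#' study sample of every group. Species kept in one group only remain in that
#' group's reporting set and are marked not-quantified (NQ) for the other
#' group, mirroring how group-specific dropouts are reported.
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param conc_matrix Samples-by-species concentration matrix from
#'   [quantify_table()] (all samples; study rows are selected via `metadata`).
#' @param metadata Sample metadata (`sample_id`, `group`, `role`).
#' @return List: `final_species`, `reporting` (named list of per-group
#'   reporting species), `matrix` (study samples by final species),
#'   `species_overall` (per-species cross-group summary with `in_final`),
#'   and the input `report`.
#' @export
finalize_dataset <- function(report, conc_matrix, metadata) {
  stopifnot(inherits(report, "qc_report"))
  groups <- unique(report$species$group)
  study <- metadata[metadata$role == "study", , drop = FALSE]

  kept_by_group <- lapply(groups, function(g) {
    dec <- report$species[report$species$group == g, ]
    kept <- dec$species[dec$decision %in% c("kept", "kept_by_override")]
    ids <- study$sample_id[study$group == g]
    ids <- intersect(ids, rownames(conc_matrix))
    complete <- kept[vapply(kept, function(sp) {
      sp %in% colnames(conc_matrix) && all(is.finite(conc_matrix[ids, sp]))
    }, logical(1))]
    complete
  })
  names(kept_by_group) <- groups

  final_species <- Reduce(intersect, kept_by_group)
  if (length(final_species) == 0L) {
    stop("no species survive QC in all groups", call. = FALSE)
  }
  study_ids <- intersect(study$sample_id, rownames(conc_matrix))
  overall <- tibble::tibble(
    species = unique(report$species$species),
    in_final = unique(report$species$species) %in% final_species
  )
  for (g in groups) {
    overall[[paste0("kept_", g)]] <- overall$species %in% kept_by_group[[g]]
  }
  list(
    final_species = final_species,
    reporting = kept_by_group,
    matrix = conc_matrix[study_ids, final_species, drop = FALSE],
    species_overall = overall,
    report = report
  )
}

#' @export
print.qc_report <- function(x, ...) {
  tab <- table(x$species$group, x$species$decision)
  cat("<qc_report>\n")
  print(tab)
  cat("\nPanel median %CV (kept species):\n")
  print(as.data.frame(x$panel_medians), row.names = FALSE)
  invisible(x)
}

#' Write a QC report to disk
#'
#' Serialises the per-species decisions as TSV and the panel medians,
#' configuration echo and override list as a JSON summary.
#'
#' @param report A `qc_report`.
#' @param tsv_path Path for the per-species TSV.
#' @param json_path Path for the JSON summary (default: `tsv_path` with a
#'   `.json` extension).
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(report, tsv_path,
                            json_path = sub("\\.tsv$", ".json", tsv_path)) {
  stopifnot(inherits(report, "qc_report"))
  readr::write_tsv(report$species, tsv_path)
  jsonlite::write_json(
    list(panel_median_pct_cv = report$panel_medians,
         config = unclass(report$config)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}
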