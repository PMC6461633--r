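#' Run the full lipidomics analysis pipeline
#'
#' Executes the stages in order on a long-format peak-area table: isotope
#' correction of the S1P d18:0 channel, internal-standard quantification,
#' the QC exclusion cascade, cross-group finalisation, paired differential
#' statistics per treatment group, double-bond saturation aggregation, and
#' the descriptive multivariate outputs (abundance PCA over all study
#' samples, log2 fold-change PCA over all subjects, Pearson/Ward
#' clustering).
#'
#' @param areas Peak-area table (`sample_id`, `species`, `panel`, `area`,
#'   `is_istd`), raw (uncorrected).
#' @param metadata Sample metadata (`sample_id`, `subject_id`, `group`,
#'   `timepoint`, `role`, `sex`).
#' @param istd_map ISTD assignment (`species`, `istd_id`, `istd_conc`).
#' @param filter A [filter_config()].
#' @param isotope List with `interferer`, `target`, `fraction` (number or
#'   `"auto"` for the carbon-only binomial default); `NULL` disables the
#'   correction.
#' @param alpha FDR significance level. Default 0.05.
#' @param fdr_scope `"group"` (default: BH across the group's full reporting
#'   set) or `"class"` (BH within each lipid class separately).
#' @param saturation_classes Class tokens for the saturation aggregates.
#' @param ward Ward variant for clustering, `"ward.D2"` or `"ward.D"`.
#' @param drop_subjects Subjects excluded from the paired analyses.
#' @return Object of class `gclipid_run`: `qc` (QC report), `final`
#'   (finalised dataset), `quant` (normalized/concentration matrices),
#'   `differential` (named list of per-group tibbles), `saturation` (named
#'   list of per-group summaries), `pca_abundance`, `pca_log2fc`,
#'   `log2fc_matrix`, `clustering`, `manifest`.
#' @export
run_pipeline <- function(areas, metadata, istd_map,
                         filter = filter_config(),
                         isotope = list(interferer = "S1P d18:1",
                                        target = "S1P d18:0",
                                        fraction = "auto"),
                         alpha = 0.05,
                         fdr_scope = c("group", "class"),
                         saturation_classes = c("PC", "PE", "PI"),
                         ward = c("ward.D2", "ward.D"),
                         drop_subjects = character(0)) {
  fdr_scope <- match.arg(fdr_scope)
  ward <- match.arg(ward)
  stopifnot(alpha > 0, alpha < 1)

  if (!is.null(isotope) &&
      isotope$target %in% areas$species &&
      isotope$interferer %in% areas$species) {
    frac <- isotope$fraction
    if (identical(frac, "auto")) {
      n_c <- parse_lipid_name(isotope$interferer)$total_carbons
      frac <- isotope_m2_fraction(n_c)
    }
    areas <- correct_s1p_interference(areas, interferer = isotope$interferer,
                                      target = isotope$target, fraction = frac)
  }

  quant <- quantify_table(areas, istd_map)
  qc <- qc_filter(areas, metadata, istd_map, filter)
  fin <- finalize_dataset(qc, quant$concentration, metadata)

  groups <- unique(metadata$group[metadata$role == "study"])
  study_ids <- metadata$sample_id[metadata$role == "study"]
  conc_study <- quant$concentration[
    intersect(rownames(quant$concentration), study_ids), , drop = FALSE]

  differential <- list()
  saturation <- list()
  for (g in groups) {
    reporting <- fin$reporting[[g]]
    dt <- differential_table(conc_study, metadata, g, species = reporting,
                             alpha = alpha, drop_subjects = drop_subjects)
    if (fdr_scope == "class") {
      cls <- parse_lipid_names(dt$species)$lipid_class
      dt$p_fdr <- unsplit(lapply(split(dt$p_raw, cls), bh_fdr), cls)
      dt$significant <- !is.na(dt$p_fdr) & dt$p_fdr <= alpha
      dt$sig_tier <- ifelse(!is.na(dt$p_fdr) & dt$p_fdr <= 0.01, "**",
                            ifelse(dt$significant, "*", ""))
    }
    differential[[g]] <- dt
    catalog_g <- parse_lipid_names(reporting)
    sat_cls <- intersect(saturation_classes, catalog_g$lipid_class)
    saturation[[g]] <- saturation_summary(
      conc_study[, reporting, drop = FALSE], metadata, g, dt,
      classes = sat_cls, catalog = catalog_g, drop_subjects = drop_subjects)
  }

  pca_ab <- pca_abundance(fin$matrix)
  l2fc <- .log2fc_matrix(fin$matrix, metadata, groups, drop_subjects)
  pca_fc <- pca_log2fc(l2fc)
  clust <- cluster_heatmap(fin$matrix, ward = ward)

  manifest <- list(
    n_species_catalog = length(unique(areas$species[!areas$is_istd])),
    n_species_final = length(fin$final_species),
    n_species_reporting = vapply(fin$reporting, length, integer(1)),
    groups = groups,
    alpha = alpha, fdr_scope = fdr_scope, ward = ward,
    drop_subjects = drop_subjects,
    filter = unclass(fin$report$config),
    isotope = if (is.null(isotope)) NULL else
      list(interferer = isotope$interferer, target = isotope$target,
           fraction = if (identical(isotope$fraction, "auto"))
             "auto (carbon-only binomial)" else isotope$fraction),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("gclipidr"))
  )

  structure(list(qc = qc, final = fin, quant = quant,
                 differential = differential, saturation = saturation,
                 pca_abundance = pca_ab, pca_log2fc = pca_fc,
                 log2fc_matrix = l2fc, clustering = clust,
                 manifest = manifest),
            class = "gclipid_run")
}

# subjects x species matrix of per-subject log2 fold changes, both groups
.log2fc_matrix <- function(conc_matrix, metadata, groups, drop_subjects) {
  rows <- list()
  for (g in groups) {
    design <- paired_design(metadata, g)
    design <- design[!design$subject_id %in% drop_subjects, , drop = FALSE]
    m <- log2(conc_matrix[design$after_sample, , drop = FALSE] /
                conc_matrix[design$before_sample, , drop = FALSE])
    rownames(m) <- design$subject_id
    rows[[g]] <- m
  }
  do.call(rbind, rows)
}

#' @export
print.gclipid_run <- function(x, ...) {
  cat("<gclipid_run>\n")
  cat("  species:", x$manifest$n_species_catalog, "measured ->",
      x$manifest$n_species_final, "in final cross-group dataset\n")
  for (g in names(x$differential)) {
    dt <- x$differential[[g]]
    cat(sprintf("  %s: %d species tested, %d significant at FDR %.2g\n",
                g, nrow(dt), sum(dt$significant, na.rm = TRUE),
                x$manifest$alpha))
  }
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Serialises the QC report, per-group differential tables, saturation
#' summaries, multivariate outputs and the run manifest.
#'
#' @param run A `gclipid_run`.
#' @param dir Output directory (created).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "gclipid_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_qc_report(run$qc, file.path(dir, "qc_report.tsv"))
  for (g in names(run$differential)) {
    p <- file.path(dir, paste0("differential_", g, ".tsv"))
    readr::write_tsv(run$differential[[g]], p)
    paths <- c(paths, p)
    sat <- run$saturation[[g]]
    ps <- file.path(dir, paste0("saturation_", g, ".tsv"))
    readr::write_tsv(sat$summary, ps)
    pj <- file.path(dir, paste0("saturation_", g, ".json"))
    jsonlite::write_json(
      lapply(sat[setdiff(names(sat), "summary")], function(s)
        s[c("p_total_LE3", "p_total_GE4", "p_ratio", "p_fc_contrast")]),
      pj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, ps, pj)
  }
  paths <- c(paths,
             write_multivariate(run$pca_abundance, run$clustering, dir,
                                prefix = "abundance"),
             write_multivariate(run$pca_log2fc, NULL, dir, prefix = "log2fc"))
  pm <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, pm, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pm))
}
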