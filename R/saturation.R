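#' Per-sample double-bond stratum totals for one lipid class
#'
#' Sums the concentrations of a class's species by saturation stratum
#' (at most 3 vs at least 4 total double bonds) in every sample. Ether and
#' plasmalogen subclasses carry their own class tokens (PC-O, PC-P, PE-O,
#' PE-P) and lyso species their own (LPC, LPE), so acyl PC/PE totals never
#' include them. A class with all species in one stratum yields 0 for the
#' other, with a warning.
#'
#' @param conc_matrix Samples-by-species concentration matrix.
#' @param lipid_class Class token, e.g. `"PC"`.
#' @param catalog Parsed catalog ([parse_lipid_names()] output or
#'   [read_catalog()]) covering the matrix columns; defaults to parsing the
#'   column names.
#' @param cutoff_low,cutoff_high Stratum cutoffs, see [saturation_group()].
#' @return Tibble: `sample_id`, `total_LE3`, `total_GE4`,
#'   `ratio_GE4_over_LE3` (NA when the LE3 total is 0).
#' @export
class_db_totals <- function(conc_matrix, lipid_class,
                            catalog = parse_lipid_names(colnames(conc_matrix)),
                            cutoff_low = 3L, cutoff_high = 4L) {
  if (!lipid_class %in% catalog$lipid_class) {
    stop("unknown or absent lipid class '", lipid_class, "'", call. = FALSE)
  }
  cat_sub <- catalog[catalog$lipid_class == lipid_class &
                       catalog$raw_name %in% colnames(conc_matrix), ,
                     drop = FALSE]
  strata <- saturation_group(cat_sub$total_double_bonds,
                             cutoff_low = cutoff_low, cutoff_high = cutoff_high)
  le3 <- cat_sub$raw_name[!is.na(strata) & strata == "LE3"]
  ge4 <- cat_sub$raw_name[!is.na(strata) & strata == "GE4"]
  if (length(le3) == 0L || length(ge4) == 0L) {
    warning("class '", lipid_class, "' has an empty ",
            if (length(le3) == 0L) "LE3" else "GE4",
            " stratum; its total is 0", call. = FALSE)
  }
  tot <- function(cols) {
    if (length(cols) == 0L) rep(0, nrow(conc_matrix))
    else unname(rowSums(conc_matrix[, cols, drop = FALSE]))
  }
  total_le3 <- tot(le3)
  total_ge4 <- tot(ge4)
  tibble::tibble(
    sample_id = rownames(conc_matrix),
    total_LE3 = total_le3,
    total_GE4 = total_ge4,
    ratio_GE4_over_LE3 = ifelse(total_le3 > 0, total_ge4 / total_le3, NA_real_)
  )
}

#' Saturation-stratum tests for one class and group
#'
#' Four paired/two-sample tests on the double-bond aggregates of one class:
#' paired two-tailed t-tests on log-transformed before/after totals of each
#' stratum, a paired t-test on the log GE4/LE3 ratio, and a two-sample Welch
#' t-test comparing the per-species mean log2 fold changes between the two
#' strata (species are the units; no pairing structure links the strata).
#'
#' @param totals Output of [class_db_totals()] over the study samples.
#' @param design Paired design for the group ([paired_design()]).
#' @param species_log2fc Tibble with `species` and `mean_log2fc` for the
#'   class's species (e.g. a [differential_table()] subset).
#' @param catalog Parsed catalog covering those species.
#' @param cutoff_low,cutoff_high Stratum cutoffs.
#' @return List of class `saturation_tests`: `p_total_LE3`, `p_total_GE4`,
#'   `p_ratio`, `p_fc_contrast`, plus `subject_totals` (per-subject wide
#'   table) and `degenerate` flags. Tests on an empty stratum are NA.
#' @export
saturation_tests <- function(totals, design, species_log2fc,
                             catalog = parse_lipid_names(species_log2fc$species),
                             cutoff_low = 3L, cutoff_high = 4L) {
  if (nrow(design) < 2L) stop("at least two subjects required", call. = FALSE)
  get <- function(col, ids) {
    totals[[col]][match(ids, totals$sample_id)]
  }
  paired_p <- function(col) {
    b <- get(col, design$before_sample)
    a <- get(col, design$after_sample)
    if (any(!is.finite(b)) || any(!is.finite(a)) || any(b <= 0) || any(a <= 0)) {
      return(NA_real_)
    }
    paired_t_log2(b, a)$p
  }
  p_le3 <- paired_p("total_LE3")
  p_ge4 <- paired_p("total_GE4")
  p_ratio <- paired_p("ratio_GE4_over_LE3")

  strata <- saturation_group(
    catalog$total_double_bonds[match(species_log2fc$species, catalog$raw_name)],
    cutoff_low = cutoff_low, cutoff_high = cutoff_high)
  x <- species_log2fc$mean_log2fc[!is.na(strata) & strata == "LE3"]
  y <- species_log2fc$mean_log2fc[!is.na(strata) & strata == "GE4"]
  p_contrast <- if (length(x) >= 2L && length(y) >= 2L &&
                      (stats::sd(x) > 0 || stats::sd(y) > 0)) {
    stats::t.test(x, y, var.equal = FALSE)$p.value
  } else {
    NA_real_
  }

  subject_totals <- tibble::tibble(
    subject_id = design$subject_id,
    LE3_before = get("total_LE3", design$before_sample),
    LE3_after = get("total_LE3", design$after_sample),
    GE4_before = get("total_GE4", design$before_sample),
    GE4_after = get("total_GE4", design$after_sample),
    ratio_before = get("ratio_GE4_over_LE3", design$before_sample),
    ratio_after = get("ratio_GE4_over_LE3", design$after_sample)
  )
  structure(list(p_total_LE3 = p_le3, p_total_GE4 = p_ge4, p_ratio = p_ratio,
                 p_fc_contrast = p_contrast, subject_totals = subject_totals),
            class = "saturation_tests")
}

#' Saturation summary across classes for one group
#'
#' Runs [class_db_totals()] and [saturation_tests()] for each requested class
#' (default the acyl glycerophospholipid classes PC, PE, PI) against one
#' group's paired design and differential results.
#'
#' @param conc_matrix Samples-by-species concentration matrix (QC-filtered).
#' @param metadata Sample metadata.
#' @param group Group label.
#' @param diff_table [differential_table()] result for the group (source of
#'   per-species mean log2 fold changes).
#' @param classes Class tokens to aggregate; default `c("PC", "PE", "PI")`.
#' @param catalog Parsed catalog; defaults to parsing the matrix columns.
#' @param drop_subjects Subjects excluded from the paired tests.
#' @return Named list (one `saturation_tests` per class) with a `summary`
#'   tibble of the four p-values per class.
#' @export
saturation_summary <- function(conc_matrix, metadata, group, diff_table,
                               classes = c("PC", "PE", "PI"),
                               catalog = parse_lipid_names(colnames(conc_matrix)),
                               drop_subjects = character(0)) {
  design <- paired_design(metadata, group)
  design <- design[!design$subject_id %in% drop_subjects, , drop = FALSE]
  per_class <- lapply(classes, function(cl) {
    totals <- class_db_totals(conc_matrix, cl, catalog = catalog)
    sp <- catalog$raw_name[catalog$lipid_class == cl]
    sl <- diff_table[diff_table$species %in% sp, c("species", "mean_log2fc")]
    saturation_tests(totals, design, sl, catalog = catalog)
  })
  names(per_class) <- classes
  per_class$summary <- tibble::tibble(
    lipid_class = classes,
    group = group,
    p_total_LE3 = vapply(per_class[classes], `[[`, numeric(1), "p_total_LE3"),
    p_total_GE4 = vapply(per_class[classes], `[[`, numeric(1), "p_total_GE4"),
    p_ratio = vapply(per_class[classes], `[[`, numeric(1), "p_ratio"),
    p_fc_contrast = vapply(per_class[classes], `[[`, numeric(1), "p_fc_contrast")
  )
  per_class
}
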