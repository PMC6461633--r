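#' Normalise a peak area by its internal standard
#'
#' Single-point internal-standard normalisation: the analyte peak area divided
#' by the peak area of the co-extracted ISTD in the same sample.
#'
#' @param area Analyte peak area(s), non-negative.
#' @param istd_area ISTD peak area(s), strictly positive.
#' @return `area / istd_area`.
#' @export
normalize_area <- function(area, istd_area) {
  if (any(!is.finite(istd_area)) || any(istd_area <= 0)) {
    stop("ISTD peak area must be strictly positive", call. = FALSE)
  }
  if (any(area < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  area / istd_area
}

#' Convert a normalised area to a relative molar concentration
#'
#' Multiplies the normalised peak area by the spiked molar concentration of
#' the assigned internal standard. This is single-point quantification with an
#' implicit response factor of 1, so the result is a relative (not absolute)
#' concentration in the ISTD's units (umol/L).
#'
#' @param normalized_area Normalised peak area(s).
#' @param istd_conc Spiked ISTD concentration(s) in umol/L, strictly positive.
#' @return Relative concentration(s) in umol/L.
#' @export
to_concentration <- function(normalized_area, istd_conc) {
  if (any(!is.finite(istd_conc)) || any(istd_conc <= 0)) {
    stop("ISTD concentration must be strictly positive", call. = FALSE)
  }
  normalized_area * istd_conc
}

#' M+2/M+0 isotopologue abundance ratio (carbon-only model)
#'
#' Fraction of a species' monoisotopic signal expected two mass units higher
#' from two 13C substitutions, under a binomial model over the carbon
#' skeleton: `choose(n, 2) * (p / (1 - p))^2`. Used as the default correction
#' factor for the M+2 cross-talk of S1P d18:1 (18 carbons) into the S1P d18:0
#' channel, where the two species differ by two mass units.
#'
#' @param carbon_count Number of carbons (>= 2).
#' @param p13C Natural 13C abundance; default 0.0107.
#' @return The M+2/M+0 abundance ratio.
#' @examples
#' isotope_m2_fraction(18)  # ~0.0179
#' @export
isotope_m2_fraction <- function(carbon_count, p13C = 0.0107) {
  if (any(carbon_count < 2) || any(carbon_count != floor(carbon_count))) {
    stop("carbon_count must be an integer >= 2", call. = FALSE)
  }
  if (p13C <= 0 || p13C >= 1) {
    stop("p13C must lie in (0, 1)", call. = FALSE)
  }
  choose(carbon_count, 2) * (p13C / (1 - p13C))^2
}

#' Subtract isotope interference from a co-measured species
#'
#' Per sample, subtracts `fraction` times the interferer's peak area from the
#' target species' area (the M+2 isotopologue of the interferer co-elutes in
#' the target's channel). Corrected areas that would go negative are clamped
#' to zero with a warning: blanks and trace-level samples legitimately carry
#' less target signal than the predicted interference.
#'
#' @param table A peak-area table: data frame with columns `sample_id`,
#'   `species`, `area` (other columns pass through).
#' @param interferer Species whose M+2 isotopologue interferes
#'   (default `"S1P d18:1"`).
#' @param target Species receiving the interference (default `"S1P d18:0"`).
#' @param fraction M+2/M+0 abundance ratio; default the carbon-only binomial
#'   ratio for 18 carbons, [isotope_m2_fraction()].
#' @return The table with corrected target areas; attribute
#'   `"isotope_correction"` holds a per-sample log (sample, interferer area,
#'   subtracted amount, clamped flag).
#' @export
correct_s1p_interference <- function(table,
                                     interferer = "S1P d18:1",
                                     target = "S1P d18:0",
                                     fraction = isotope_m2_fraction(18L)) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "species", "area") %in% names(table)))
  if (fraction < 0) stop("fraction must be non-negative", call. = FALSE)
  idx_t <- which(table$species == target)
  if (length(idx_t) == 0L || fraction == 0) {
    attr(table, "isotope_correction") <- tibble::tibble(
      sample_id = character(0), interferer_area = numeric(0),
      subtracted = numeric(0), clamped = logical(0))
    return(table)
  }
  idx_i <- which(table$species == interferer)
  int_area <- table$area[idx_i]
  names(int_area) <- table$sample_id[idx_i]
  miss <- setdiff(table$sample_id[idx_t], names(int_area))
  if (length(miss) > 0L) {
    stop("interferer '", interferer, "' missing in sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sub <- unname(fraction * int_area[table$sample_id[idx_t]])
  corrected <- table$area[idx_t] - sub
  clamped <- corrected < 0
  if (any(clamped)) {
    warning(sum(clamped), " corrected area(s) of '", target,
            "' were negative and clamped to 0", call. = FALSE)
    corrected[clamped] <- 0
  }
  log_df <- tibble::tibble(
    sample_id = table$sample_id[idx_t],
    interferer_area = unname(int_area[table$sample_id[idx_t]]),
    subtracted = unname(sub),
    clamped = clamped
  )
  table$area[idx_t] <- corrected
  attr(table, "isotope_correction") <- log_df
  table
}

#' Quantify a peak-area table against its internal standards
#'
#' Converts a long-format peak-area table into two samples-by-species
#' matrices: ISTD-normalised areas and relative molar concentrations. Every
#' sample (study, pooled QC and blank alike) is normalised against its own
#' ISTD areas, so instrument drift and injection variation cancel per sample.
#' Any isotope-interference correction must be applied beforehand.
#'
#' @param table Peak-area table: data frame with columns `sample_id`,
#'   `species`, `area`, and logical `is_istd` marking internal-standard rows.
#' @param istd_map Data frame with columns `species`, `istd_id`,
#'   `istd_conc` (umol/L, > 0): the ISTD assignment for every analyte species.
#' @return A list with elements `normalized` and `concentration`, each a
#'   numeric matrix (samples in rows, analyte species in columns, both sorted
#'   by first appearance in `table`) carrying a `"provenance"` attribute.
#' @export
quantify_table <- function(table, istd_map) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "species", "area", "is_istd") %in% names(table)))
  stopifnot(all(c("species", "istd_id", "istd_conc") %in% names(istd_map)))
  if (any(istd_map$istd_conc <= 0)) {
    stop("ISTD concentrations must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(istd_map$species)) {
    stop("each species must map to exactly one ISTD", call. = FALSE)
  }
  if (anyDuplicated(table[, c("sample_id", "species")])) {
    stop("(sample_id, species) pairs must be unique", call. = FALSE)
  }

  analytes <- table[!table$is_istd, , drop = FALSE]
  istds <- table[table$is_istd, , drop = FALSE]
  unmapped <- setdiff(unique(analytes$species), istd_map$species)
  if (length(unmapped) > 0L) {
    stop("species without ISTD mapping: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }

  samples <- unique(table$sample_id)
  species <- unique(analytes$species)
  map_idx <- match(analytes$species, istd_map$species)
  istd_id <- istd_map$istd_id[map_idx]
  istd_conc <- istd_map$istd_conc[map_idx]

  istd_key <- paste(istds$sample_id, istds$species, sep = "\r")
  istd_area <- istds$area[match(paste(analytes$sample_id, istd_id, sep = "\r"),
                                istd_key)]
  if (any(is.na(istd_area))) {
    bad <- unique(paste0(analytes$sample_id, " / ", istd_id)[is.na(istd_area)])
    stop("missing ISTD area for: ", paste(utils::head(bad, 5), collapse = "; "),
         call. = FALSE)
  }
  if (any(istd_area <= 0)) {
    bad <- unique(paste0(analytes$sample_id, " / ", istd_id)[istd_area <= 0])
    stop("non-positive ISTD area for: ", paste(utils::head(bad, 5), collapse = "; "),
         call. = FALSE)
  }

  norm <- matrix(NA_real_, nrow = length(samples), ncol = length(species),
                 dimnames = list(samples, species))
  conc <- norm
  ri <- match(analytes$sample_id, samples)
  ci <- match(analytes$species, species)
  norm[cbind(ri, ci)] <- analytes$area / istd_area
  conc[cbind(ri, ci)] <- analytes$area / istd_area * istd_conc
  attr(norm, "provenance") <- "normalized_area"
  attr(conc, "provenance") <- "concentration"
  list(normalized = norm, concentration = conc)
}
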