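# Plain-text tabular I/O: UTF-8, tab separator, '.' decimal.

#' Read a long-format peak-area table
#'
#' Columns: `sample_id`, `species`, `panel`, `area`, and optionally
#' `is_istd` (inferred from the ISTD map's `istd_id`s when absent).
#'
#' @param path TSV/CSV path (delimiter inferred from extension).
#' @param istd_ids Optional character vector of ISTD identifiers used to
#'   infer `is_istd` when the column is missing.
#' @return Tibble peak-area table.
#' @export
read_peak_areas <- function(path, istd_ids = NULL) {
  df <- .read_delim_auto(path)
  need <- c("sample_id", "species", "panel", "area")
  if (!all(need %in% names(df))) {
    stop("peak-area table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$area <- as.numeric(df$area)
  if (any(df$area < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  if (!"is_istd" %in% names(df)) {
    if (is.null(istd_ids)) {
      stop("provide an is_istd column or istd_ids to infer it", call. = FALSE)
    }
    df$is_istd <- df$species %in% istd_ids
  } else {
    df$is_istd <- as.logical(df$is_istd)
  }
  df
}

#' Read a sample-metadata table
#'
#' Columns: `sample_id`, `subject_id`, `group`, `timepoint`
#' (`before`/`after`, empty for QC samples), `role`
#' (`study`/`PQC`/`blank`), `sex`.
#'
#' @param path TSV/CSV path.
#' @return Tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- .read_delim_auto(path)
  need <- c("sample_id", "subject_id", "group", "timepoint", "role")
  if (!all(need %in% names(df))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(df$role %in% c("study", "PQC", "blank"))) {
    stop("role must be one of study, PQC, blank", call. = FALSE)
  }
  df
}

#' Read an internal-standard map
#'
#' Columns: `species`, `istd_id`, `istd_conc` (accepted alias:
#' `istd_conc_umol_per_L`).
#'
#' @param path TSV/CSV path.
#' @return Tibble with `species`, `istd_id`, `istd_conc`.
#' @export
read_istd_map <- function(path) {
  df <- .read_delim_auto(path)
  if ("istd_conc_umol_per_L" %in% names(df) && !"istd_conc" %in% names(df)) {
    df$istd_conc <- df$istd_conc_umol_per_L
  }
  need <- c("species", "istd_id", "istd_conc")
  if (!all(need %in% names(df))) {
    stop("ISTD map needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$istd_conc <- as.numeric(df$istd_conc)
  df[, need]
}

#' Read a paired clinical-chemistry table
#'
#' Columns: `analyte`, `subject_id`, `before`, `after`. Unicode minus signs
#' (as exported by some spreadsheets) are normalised to ASCII hyphen-minus
#' before numeric conversion.
#'
#' @param path TSV/CSV path.
#' @return Tibble suitable for [paired_panel_summary()].
#' @export
read_paired_clinical <- function(path) {
  df <- .read_delim_auto(path, all_character = TRUE)
  need <- c("analyte", "subject_id", "before", "after")
  if (!all(need %in% names(df))) {
    stop("clinical table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  fix <- function(x) as.numeric(gsub("−", "-", x))
  df$before <- fix(df$before)
  df$after <- fix(df$after)
  df
}

.read_delim_auto <- function(path, all_character = FALSE) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ct <- if (all_character) readr::cols(.default = "c") else readr::cols()
  readr::read_delim(path, delim = delim, col_types = ct,
                    locale = readr::locale(decimal_mark = "."),
                    progress = FALSE, show_col_types = FALSE)
}

#' Write a samples-by-species matrix as TSV
#'
#' Wide layout with samples in rows and species in columns. When `panels` is
#' supplied, a second header line starting with `#panel` records each
#' species' analytical panel.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param panels Optional named character vector (species -> panel).
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path, panels = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(mat)), collapse = "\t"), con)
  if (!is.null(panels)) {
    writeLines(paste(c("#panel", unname(panels[colnames(mat)])),
                     collapse = "\t"), con)
  }
  body <- apply(mat, 1L, function(r)
    paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a samples-by-species matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return Numeric matrix; a `#panel` header line, if present, is attached
#'   as the `"panels"` attribute.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  panels <- NULL
  body_start <- 2L
  if (length(lines) >= 2L && startsWith(lines[2L], "#panel")) {
    pl <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][-1L]
    panels <- stats::setNames(pl, header[-1L])
    body_start <- 3L
  }
  rows <- strsplit(lines[seq(body_start, length(lines))], "\t", fixed = TRUE)
  mat <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                  numeric(length(header) - 1L)))
  rownames(mat) <- vapply(rows, `[[`, character(1), 1L)
  colnames(mat) <- header[-1L]
  attr(mat, "panels") <- panels
  mat
}

#' Write a synthetic experiment to a dataset directory
#'
#' Serialises the generator output in the same dialects the pipeline reads:
#' `areas.tsv`, `metadata.tsv`, `istd_map.tsv`, `catalog.tsv`, plus the
#' ground truth as a separate `ground_truth.json` so analysis inputs never
#' contain the truth.
#'
#' @param sim A `synthetic_experiment` from [simulate_experiment()], or a
#'   `simulation_config` (then simulated first).
#' @param dir Output directory (created).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  if (inherits(sim, "simulation_config")) sim <- simulate_experiment(sim)
  stopifnot(inherits(sim, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    areas = file.path(dir, "areas.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    istd_map = file.path(dir, "istd_map.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(sim$areas, paths[["areas"]])
  readr::write_tsv(sim$metadata, paths[["metadata"]])
  readr::write_tsv(sim$istd_map, paths[["istd_map"]])
  readr::write_tsv(
    tibble::tibble(species_name = sim$catalog$species_name,
                   panel = sim$catalog$panel,
                   istd_id = sim$catalog$istd_id),
    paths[["catalog"]])
  truth <- sim$truth
  truth$config <- truth$config[c("seed", "blank_fraction", "n_pqc_replicates",
                                 "n_blanks", "s1p_m2_fraction",
                                 "biological_cv_pct", "istd_conc")]
  jsonlite::write_json(truth, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
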