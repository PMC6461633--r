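#' Lipid class vocabulary
#'
#' The closed set of lipid class tokens recognised by [parse_lipid_name()].
#' The vocabulary covers the twenty classes measured on the four analytical
#' panels: sphingolipids (Cer, Hex1Cer, Hex2Cer, GM3, SM, S1P),
#' glycerophospholipids and their lyso/ether/plasmalogen variants
#' (LPC, LPC-O, PC, PC-O, PC-P, LPE, PE, PE-O, PE-P, PI, PS), glycerolipids
#' (DG, TG) and cholesteryl esters (CE). Ether ("-O") and plasmalogen ("-P")
#' subclasses are distinct class tokens, so e.g. PC-O species never
#' contribute to acyl PC aggregates.
#'
#' @return Character vector of class tokens.
#' @export
lipid_classes <- function() {
  c("Cer", "Hex1Cer", "Hex2Cer", "GM3", "SM", "S1P",
    "LPC", "LPC-O", "PC", "PC-O", "PC-P",
    "LPE", "PE", "PE-O", "PE-P", "PI", "PS",
    "DG", "TG", "CE")
}

# classes whose species may carry a sphingoid base token (dC:D)
.sphingoid_classes <- c("Cer", "Hex1Cer", "Hex2Cer", "GM3", "SM", "S1P")

.chain_rx <- "^([0-9]+):([0-9]+)$"
.base_rx <- "^d([0-9]+):([0-9]+)$"

#' Parse a lipid shorthand name
#'
#' Decomposes a species name such as `"Cer d18:1/18:0"`, `"DG 18:0_18:2"` or
#' `"PC 38:4"` into its class token, linkage, optional sphingoid base,
#' fatty-acyl chains and carbon/double-bond totals. The chain separator
#' records how much structural detail the name asserts: `"/"` for known
#' sn-positions, `"_"` for unknown sn-positions, and sum-composition for a
#' single combined chain token. Totals include the sphingoid base, so
#' `Cer d18:1/18:0` has 36 carbons and 1 double bond.
#'
#' @param name A single species name (class token, one space, chain spec).
#' @param classes Class vocabulary; defaults to the closed set in
#'   [lipid_classes()] but can be extended for non-standard panels.
#' @return An object of class `parsed_lipid`: a list with fields `raw_name`,
#'   `lipid_class`, `linkage` (`"acyl"`, `"ether"`, `"plasmalogen"`),
#'   `sphingoid_base` (list with `carbons`, `double_bonds`, or `NULL`),
#'   `chains` (data frame with `carbons`, `double_bonds`),
#'   `chain_separator` (`"slash_known_sn"`, `"underscore_unknown_sn"`,
#'   `"sum_composition"`), `total_carbons`, `total_double_bonds`.
#' @examples
#' p <- parse_lipid_name("Cer d18:1/18:0")
#' p$total_carbons       # 36
#' p$total_double_bonds  # 1
#' format(p)             # round-trips the input
#' @export
parse_lipid_name <- function(name, classes = lipid_classes()) {
  if (length(name) != 1L || !is.character(name) || is.na(name) || !nzchar(name)) {
    stop("lipid name must be a single non-empty string", call. = FALSE)
  }
  sp <- regexpr(" ", name, fixed = TRUE)
  if (sp < 0L) {
    stop("malformed lipid name '", name, "': expected '<class> <chains>'",
         call. = FALSE)
  }
  class_tok <- substr(name, 1L, sp - 1L)
  chain_str <- substr(name, sp + 1L, nchar(name))
  if (!class_tok %in% classes) {
    stop("unrecognized lipid class token '", class_tok, "' in '", name, "'",
         call. = FALSE)
  }
  if (!nzchar(chain_str) || grepl(" ", chain_str, fixed = TRUE)) {
    stop("malformed chain specification '", chain_str, "' in '", name, "'",
         call. = FALSE)
  }

  linkage <- if (endsWith(class_tok, "-O")) "ether"
             else if (endsWith(class_tok, "-P")) "plasmalogen"
             else "acyl"

  if (grepl("/", chain_str, fixed = TRUE) && grepl("_", chain_str, fixed = TRUE)) {
    stop("mixed chain separators in '", name, "'", call. = FALSE)
  }
  sep_chr <- if (grepl("/", chain_str, fixed = TRUE)) "/"
             else if (grepl("_", chain_str, fixed = TRUE)) "_"
             else ""
  toks <- if (sep_chr == "") chain_str else strsplit(chain_str, sep_chr, fixed = TRUE)[[1]]
  if (any(!nzchar(toks))) {
    stop("empty chain token in '", name, "'", call. = FALSE)
  }

  base <- NULL
  if (grepl(.base_rx, toks[1L])) {
    if (!class_tok %in% .sphingoid_classes) {
      stop("sphingoid base token '", toks[1L], "' not allowed for class '",
           class_tok, "' in '", name, "'", call. = FALSE)
    }
    m <- regmatches(toks[1L], regexec(.base_rx, toks[1L]))[[1L]]
    base <- list(carbons = as.integer(m[2L]), double_bonds = as.integer(m[3L]))
    toks <- toks[-1L]
  }

  chains <- data.frame(carbons = integer(0), double_bonds = integer(0))
  if (length(toks) > 0L) {
    bad <- toks[!grepl(.chain_rx, toks)]
    if (length(bad) > 0L) {
      stop("malformed chain spec '", bad[1L], "' in '", name, "'", call. = FALSE)
    }
    mm <- regmatches(toks, regexec(.chain_rx, toks))
    chains <- data.frame(
      carbons = vapply(mm, function(m) as.integer(m[2L]), integer(1)),
      double_bonds = vapply(mm, function(m) as.integer(m[3L]), integer(1))
    )
  }
  if (is.null(base) && nrow(chains) == 0L) {
    stop("no chains found in '", name, "'", call. = FALSE)
  }

  n_tokens <- nrow(chains) + !is.null(base)
  separator <- if (n_tokens <= 1L) "sum_composition"
               else if (sep_chr == "/") "slash_known_sn"
               else "underscore_unknown_sn"

  out <- list(
    raw_name = name,
    lipid_class = class_tok,
    linkage = linkage,
    sphingoid_base = base,
    chains = chains,
    chain_separator = separator,
    total_carbons = sum(chains$carbons) + if (is.null(base)) 0L else base$carbons,
    total_double_bonds = sum(chains$double_bonds) +
      if (is.null(base)) 0L else base$double_bonds
  )
  class(out) <- "parsed_lipid"
  out
}

#' @export
format.parsed_lipid <- function(x, ...) {
  toks <- character(0)
  if (!is.null(x$sphingoid_base)) {
    toks <- sprintf("d%d:%d", x$sphingoid_base$carbons, x$sphingoid_base$double_bonds)
  }
  if (nrow(x$chains) > 0L) {
    toks <- c(toks, sprintf("%d:%d", x$chains$carbons, x$chains$double_bonds))
  }
  sep <- switch(x$chain_separator,
    slash_known_sn = "/", underscore_unknown_sn = "_", sum_composition = "")
  paste(x$lipid_class, paste(toks, collapse = sep))
}

#' @export
print.parsed_lipid <- function(x, ...) {
  cat(sprintf("<parsed_lipid> %s\n  class %s (%s), C%d:%d, separator %s\n",
              x$raw_name, x$lipid_class, x$linkage,
              x$total_carbons, x$total_double_bonds, x$chain_separator))
  invisible(x)
}

#' Parse many lipid names into a tibble
#'
#' Vectorised companion to [parse_lipid_name()], returning one row per name
#' with the structured fields flattened. This is the form consumed by the
#' aggregation and filtering stages.
#'
#' @param names Character vector of species names.
#' @inheritParams parse_lipid_name
#' @return A tibble with columns `raw_name`, `lipid_class`, `linkage`,
#'   `base_carbons`, `base_double_bonds` (NA when no sphingoid base),
#'   `n_chains`, `chain_separator`, `total_carbons`, `total_double_bonds`.
#' @export
parse_lipid_names <- function(names, classes = lipid_classes()) {
  parsed <- lapply(names, parse_lipid_name, classes = classes)
  tibble::tibble(
    raw_name = names,
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    linkage = vapply(parsed, `[[`, character(1), "linkage"),
    base_carbons = vapply(parsed, function(p)
      if (is.null(p$sphingoid_base)) NA_integer_ else p$sphingoid_base$carbons,
      integer(1)),
    base_double_bonds = vapply(parsed, function(p)
      if (is.null(p$sphingoid_base)) NA_integer_ else p$sphingoid_base$double_bonds,
      integer(1)),
    n_chains = vapply(parsed, function(p) nrow(p$chains), integer(1)),
    chain_separator = vapply(parsed, `[[`, character(1), "chain_separator"),
    total_carbons = vapply(parsed, function(p) as.integer(p$total_carbons), integer(1)),
    total_double_bonds = vapply(parsed, function(p)
      as.integer(p$total_double_bonds), integer(1))
  )
}

#' Saturation stratum of a species
#'
#' Assigns a species to the low- (`"LE3"`, at most `cutoff_low` double bonds)
#' or high-unsaturation (`"GE4"`, at least `cutoff_high`) stratum used for the
#' class-level double-bond aggregates. With the default cutoffs 3 and 4 the
#' mapping is total; with a gap between the cutoffs, species falling in the
#' gap return `NA`.
#'
#' @param parsed A `parsed_lipid`, a species name, or a vector of names.
#' @param cutoff_low Upper bound (inclusive) of the low stratum. Default 3.
#' @param cutoff_high Lower bound (inclusive) of the high stratum. Default 4.
#' @return Character vector of `"LE3"` / `"GE4"` (or `NA` in a cutoff gap).
#' @examples
#' saturation_group("PI 38:4")  # "GE4"
#' saturation_group("PC 38:3")  # "LE3"
#' @export
saturation_group <- function(parsed, cutoff_low = 3L, cutoff_high = 4L) {
  if (cutoff_low >= cutoff_high) {
    stop("cutoff_low must be strictly less than cutoff_high", call. = FALSE)
  }
  db <- if (inherits(parsed, "parsed_lipid")) {
    parsed$total_double_bonds
  } else if (is.character(parsed)) {
    parse_lipid_names(parsed)$total_double_bonds
  } else if (is.numeric(parsed)) {
    parsed
  } else {
    stop("parsed must be a parsed_lipid, species name(s) or double-bond counts",
         call. = FALSE)
  }
  if (any(db < 0)) stop("double-bond counts must be non-negative", call. = FALSE)
  out <- rep(NA_character_, length(db))
  out[db <= cutoff_low] <- "LE3"
  out[db >= cutoff_high] <- "GE4"
  out
}

#' Read a species catalog
#'
#' Reads a tab-separated species catalog with columns `species_name`, `panel`
#' and `istd_id`, parses every name, and returns the catalog with the derived
#' structural fields attached. Parsed fields are always derived from the name,
#' never stored in the file.
#'
#' @param path Path to a TSV file.
#' @inheritParams parse_lipid_name
#' @return A tibble: the file's columns joined with [parse_lipid_names()].
#' @export
read_catalog <- function(path, classes = lipid_classes()) {
  cat_df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("species_name", "panel", "istd_id")
  if (!all(need %in% names(cat_df))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_lipid_names(cat_df$species_name, classes = classes)
  dplyr::bind_cols(cat_df, parsed[, setdiff(names(parsed), "raw_name")])
}
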