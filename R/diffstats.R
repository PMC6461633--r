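#' Per-subject log2 fold change
#'
#' `log2(after / before)` for one subject and analyte; both values must be
#' strictly positive (concentrations on the relative molar scale).
#'
#' @param before,after Positive concentration(s), subject-aligned.
#' @param label Optional label (subject/analyte) used in error messages.
#' @return log2 fold change(s).
#' @export
per_subject_log2fc <- function(before, after, label = NULL) {
  bad <- !is.finite(before) | !is.finite(after) | before <= 0 | after <= 0
  if (any(bad)) {
    stop("non-positive or missing value in paired concentrations",
         if (!is.null(label)) paste0(" (", label, ")") else "", call. = FALSE)
  }
  log2(after / before)
}

#' Signed fold-change display convention
#'
#' Back-transforms a mean log2 fold change to the signed fold scale used in
#' the result tables: increases as `2^x` (so +1 -> 2.0), decreases as the
#' negative reciprocal `-2^(-x)` (so -1 -> -2.0, "halved"). Zero maps to +1.
#'
#' @param mean_log2fc Numeric vector of log2 fold changes.
#' @return Signed fold changes.
#' @export
signed_fold_change <- function(mean_log2fc) {
  ifelse(mean_log2fc >= 0, 2^mean_log2fc, -(2^(-mean_log2fc)))
}

#' Paired two-tailed t-test on log2 values
#'
#' Tests the per-subject differences `d_i = log2(after_i) - log2(before_i)`
#' against zero with a Student t on `n - 1` degrees of freedom. When all
#' differences are identical (zero sample variance) the p-value is undefined
#' and the result is flagged degenerate rather than reported as significant.
#'
#' @param before,after Positive vectors of equal length `n >= 2`,
#'   subject-aligned.
#' @return List: `t`, `df`, `p` (NA when degenerate), `mean_log2fc`,
#'   `degenerate`.
#' @export
paired_t_log2 <- function(before, after) {
  if (length(before) != length(after)) {
    stop("before and after must be subject-aligned vectors of equal length",
         call. = FALSE)
  }
  n <- length(before)
  if (n < 2L) stop("paired t-test requires n >= 2", call. = FALSE)
  d <- per_subject_log2fc(before, after)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_log2fc = mean(d), degenerate = TRUE))
  }
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, df = n - 1L,
       p = 2 * stats::pt(abs(tval), df = n - 1L, lower.tail = FALSE),
       mean_log2fc = mean(d), degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment. Undefined (NA) entries are
#' excluded from the family size `m` and returned as NA; input order is
#' preserved and adjusted values never fall below the raw ones.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Build the paired design from sample metadata
#'
#' Extracts the subject-level before/after sample pairing for one group.
#'
#' @param metadata Sample metadata with `sample_id`, `subject_id`, `group`,
#'   `timepoint` (`"before"`/`"after"`), `role`.
#' @param group Group label.
#' @return Tibble: `subject_id`, `before_sample`, `after_sample`, `sex`
#'   (if present).
#' @export
paired_design <- function(metadata, group) {
  st <- metadata[metadata$role == "study" & metadata$group == group, ,
                 drop = FALSE]
  subjects <- unique(st$subject_id)
  pick <- function(subj, tp) {
    id <- st$sample_id[st$subject_id == subj & st$timepoint == tp]
    if (length(id) != 1L) {
      stop("subject '", subj, "' must have exactly one '", tp, "' sample",
           call. = FALSE)
    }
    id
  }
  tibble::tibble(
    subject_id = subjects,
    before_sample = vapply(subjects, pick, character(1), tp = "before"),
    after_sample = vapply(subjects, pick, character(1), tp = "after"),
    sex = if ("sex" %in% names(st))
      st$sex[match(subjects, st$subject_id)] else NA_character_
  )
}

#' Paired differential table for one treatment group
#'
#' For every species: per-subject log2 fold changes, their mean, the signed
#' average fold change (geometric mean of the after/before ratios on the
#' signed display scale), the paired two-tailed t-test on log2 concentrations
#' and the BH-FDR adjusted p-value across all species of the group's
#' reporting set. Significance is called at `p_fdr <= alpha`, with a
#' two-star tier at `p_fdr <= 0.01`.
#'
#' @param conc_matrix Samples-by-species concentration matrix (QC-filtered).
#' @param metadata Sample metadata (see [paired_design()]).
#' @param group Group label.
#' @param species Species to analyse; default all columns of `conc_matrix`.
#' @param alpha FDR significance level, default 0.05.
#' @param drop_subjects Subjects to exclude before testing (sensitivity
#'   analyses), default none.
#' @return Tibble, one row per species: `species`, `group`, `n`,
#'   `mean_log2fc`, `fc` (signed), `p_raw`, `p_fdr`, `significant`,
#'   `sig_tier` (`""`, `"*"`, `"**"`), then one `log2FC_<subject>` column per
#'   subject.
#' @export
differential_table <- function(conc_matrix, metadata, group,
                               species = colnames(conc_matrix),
                               alpha = 0.05, drop_subjects = character(0)) {
  design <- paired_design(metadata, group)
  design <- design[!design$subject_id %in% drop_subjects, , drop = FALSE]
  miss <- setdiff(c(design$before_sample, design$after_sample),
                  rownames(conc_matrix))
  if (length(miss) > 0L) {
    stop("samples missing from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  before <- conc_matrix[design$before_sample, species, drop = FALSE]
  after <- conc_matrix[design$after_sample, species, drop = FALSE]

  res <- lapply(seq_along(species), function(j) {
    tt <- paired_t_log2(before[, j], after[, j])
    d <- per_subject_log2fc(before[, j], after[, j])
    list(p = tt$p, mean = tt$mean_log2fc, d = d)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p")
  mean_l2fc <- vapply(res, `[[`, numeric(1), "mean")
  p_fdr <- bh_fdr(p_raw)

  out <- tibble::tibble(
    species = species,
    group = group,
    n = nrow(design),
    mean_log2fc = mean_l2fc,
    fc = signed_fold_change(mean_l2fc),
    p_raw = p_raw,
    p_fdr = p_fdr,
    significant = !is.na(p_fdr) & p_fdr <= alpha,
    sig_tier = dplyr::case_when(
      !is.na(p_fdr) & p_fdr <= 0.01 ~ "**",
      !is.na(p_fdr) & p_fdr <= alpha ~ "*",
      TRUE ~ ""
    )
  )
  l2fc <- do.call(rbind, lapply(res, `[[`, "d"))
  colnames(l2fc) <- paste0("log2FC_", design$subject_id)
  dplyr::bind_cols(out, tibble::as_tibble(l2fc))
}

#' Paired summary of a clinical-chemistry panel
#'
#' Per analyte: the median fold change across subjects on the signed display
#' scale (each subject's after/before ratio is sign-transformed, then the
#' median is taken) and the unadjusted p-value of the paired two-tailed
#' t-test on log2 values. Clinical panels report single-test p-values, so no
#' FDR adjustment is applied here.
#'
#' @param values Tibble with columns `analyte`, `subject_id`, `before`,
#'   `after` (positive values).
#' @return Tibble: `analyte`, `n`, `median_fc` (signed), `p_raw`.
#' @export
paired_panel_summary <- function(values) {
  stopifnot(all(c("analyte", "subject_id", "before", "after") %in% names(values)))
  analytes <- unique(values$analyte)
  rows <- lapply(analytes, function(a) {
    sub <- values[values$analyte == a, , drop = FALSE]
    fc <- sub$after / sub$before
    signed <- ifelse(fc >= 1, fc, -1 / fc)
    tt <- paired_t_log2(sub$before, sub$after)
    tibble::tibble(analyte = a, n = nrow(sub),
                   median_fc = stats::median(signed), p_raw = tt$p)
  })
  dplyr::bind_rows(rows)
}
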