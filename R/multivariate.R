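# deterministic sign convention: each component's largest-|loading| positive
.fix_pca_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

.pca_core <- function(X, preprocessing) {
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(nrow(X) - 1L, ncol(X))
  ev <- pc$sdev^2
  ve <- 100 * ev / sum(ev)
  fixed <- .fix_pca_signs(pc$x[, seq_len(k), drop = FALSE],
                          pc$rotation[, seq_len(k), drop = FALSE])
  structure(list(
    scores = fixed$scores,
    loadings = fixed$loadings,
    variance_explained = ve[seq_len(k)],
    preprocessing = preprocessing
  ), class = "pca_result")
}

#' PCA of log2 lipid abundances
#'
#' Principal component analysis of log2-transformed concentrations after
#' per-species centring and unit-variance scaling (correlation-mode PCA, via
#' singular value decomposition). Components are reported up to
#' `min(n - 1, p)` with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param conc_matrix Samples-by-species matrix of positive concentrations,
#'   at least 3 samples, no missing values.
#' @return `pca_result`: `scores` (samples x components), `loadings`
#'   (species x components), `variance_explained` (%, sums to 100 over all
#'   components), `preprocessing` record.
#' @export
pca_abundance <- function(conc_matrix) {
  if (nrow(conc_matrix) < 3L) stop("PCA requires at least 3 samples", call. = FALSE)
  if (any(!is.finite(conc_matrix)) || any(conc_matrix <= 0)) {
    stop("concentrations must be positive and complete", call. = FALSE)
  }
  L <- log2(conc_matrix)
  sds <- apply(L, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant species after log2 (scale undefined): ",
         paste(colnames(L)[sds == 0], collapse = ", "), call. = FALSE)
  }
  X <- scale(L, center = TRUE, scale = TRUE)
  .pca_core(X, list(log2 = TRUE, centred = TRUE, scaled = TRUE))
}

#' PCA of per-subject log2 fold changes
#'
#' As [pca_abundance()], but the input is already on the log2 fold-change
#' scale (subjects in rows, species in columns); only centring and scaling
#' are applied.
#'
#' @param log2fc_matrix Subjects-by-species matrix of log2 fold changes.
#' @return A `pca_result`.
#' @export
pca_log2fc <- function(log2fc_matrix) {
  if (nrow(log2fc_matrix) < 3L) stop("PCA requires at least 3 subjects", call. = FALSE)
  if (any(!is.finite(log2fc_matrix))) {
    stop("log2 fold changes must be complete", call. = FALSE)
  }
  sds <- apply(log2fc_matrix, 2L, stats::sd)
  if (all(sds == 0)) {
    stop("zero total variance: all subjects have identical fold-change profiles",
         call. = FALSE)
  }
  if (any(sds == 0)) {
    stop("constant species column(s) (scale undefined): ",
         paste(colnames(log2fc_matrix)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  X <- scale(log2fc_matrix, center = TRUE, scale = TRUE)
  .pca_core(X, list(log2 = FALSE, centred = TRUE, scaled = TRUE))
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$variance_explained))
  cat("<pca_result>", nrow(x$scores), "samples x", nrow(x$loadings), "species\n")
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), x$variance_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pearson distance
#'
#' `1 - r` over the rows of a matrix, the correlation-based dissimilarity
#' used for both heatmap axes. Ranges from 0 (perfectly correlated) to 2
#' (perfectly anticorrelated).
#'
#' @param x Matrix; distances are computed between rows.
#' @return A `dist` object.
#' @export
pearson_dist <- function(x) {
  stats::as.dist(1 - stats::cor(t(x)))
}

#' Hierarchical clustering with per-species autoscaling
#'
#' Reproduces the dual-dendrogram heatmap computation: species rows are
#' autoscaled to z-scores of their log2 concentrations, distances on both
#' axes are Pearson (`1 - r`), and agglomeration uses a Ward variant
#' (`ward.D2` by default; `ward.D` selectable as the historical variant).
#' Ties are broken deterministically by input order via [stats::hclust()].
#'
#' @param conc_matrix Samples-by-species matrix of positive concentrations,
#'   at least 2 samples and 2 species.
#' @param ward Ward variant, `"ward.D2"` (default) or `"ward.D"`.
#' @return `cluster_result`: `species_hclust`, `sample_hclust` (both
#'   `hclust`), `autoscaled` (species x samples z-score matrix), `distance`
#'   and `linkage` labels.
#' @export
cluster_heatmap <- function(conc_matrix, ward = c("ward.D2", "ward.D")) {
  ward <- match.arg(ward)
  if (nrow(conc_matrix) < 2L || ncol(conc_matrix) < 2L) {
    stop("clustering requires at least 2 samples and 2 species", call. = FALSE)
  }
  if (any(!is.finite(conc_matrix)) || any(conc_matrix <= 0)) {
    stop("concentrations must be positive and complete", call. = FALSE)
  }
  L <- t(log2(conc_matrix))            # species x samples
  sds <- apply(L, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance species row(s): ",
         paste(rownames(L)[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- t(scale(t(L)))                  # per-species z-scores of log2 values
  species_hc <- stats::hclust(pearson_dist(Z), method = ward)
  sample_hc <- stats::hclust(pearson_dist(t(Z)), method = ward)
  structure(list(species_hclust = species_hc, sample_hclust = sample_hc,
                 autoscaled = Z, distance = "pearson (1 - r)", linkage = ward),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$autoscaled), "species x",
      ncol(x$autoscaled), "samples;", x$distance, "distance,",
      x$linkage, "linkage\n")
  invisible(x)
}

#' Write multivariate outputs to disk
#'
#' Serialises PCA scores/loadings as TSV, dendrograms as Newick text and the
#' autoscaled heatmap matrix as TSV.
#'
#' @param pca A `pca_result` (or NULL to skip).
#' @param clust A `cluster_result` (or NULL to skip).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_multivariate <- function(pca = NULL, clust = NULL, dir, prefix = "mv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  as_tsv <- function(m, what) {
    p <- file.path(dir, paste0(prefix, "_", what, ".tsv"))
    df <- tibble::as_tibble(m, rownames = "id")
    readr::write_tsv(df, p)
    p
  }
  if (!is.null(pca)) {
    paths <- c(paths, as_tsv(pca$scores, "scores"), as_tsv(pca$loadings, "loadings"))
    pve <- file.path(dir, paste0(prefix, "_variance_explained.tsv"))
    readr::write_tsv(tibble::tibble(component = seq_along(pca$variance_explained),
                                    pct_variance = pca$variance_explained), pve)
    paths <- c(paths, pve)
  }
  if (!is.null(clust)) {
    for (ax in c("species", "sample")) {
      hc <- clust[[paste0(ax, "_hclust")]]
      p <- file.path(dir, paste0(prefix, "_", ax, "_dendrogram.nwk"))
      ape::write.tree(ape::as.phylo(hc), file = p)
      paths <- c(paths, p)
    }
    paths <- c(paths, as_tsv(clust$autoscaled, "autoscaled"))
  }
  invisible(paths)
}
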