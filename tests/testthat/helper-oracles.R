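# Independent oracles and fixture builders shared across the test files.
# These deliberately use naive, literal implementations so they stay
# independent of the package code paths they check.

# Literal Benjamini-Hochberg: adj_i = min over {j : p_j >= p_i} of
# min(1, p_j * m / rank_j), computed with explicit loops.
brute_force_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- vapply(which(p >= p[i]), function(j) {
      min(1, p[j] * m / rank(p, ties.method = "max")[j])
    }, numeric(1))
    min(cand)
  }, numeric(1))
}

# Closed-form two-sided p of the Student t with 2 degrees of freedom:
# F(t) = 1/2 + t / (2 * sqrt(2 + t^2))
p_two_sided_df2 <- function(t) {
  2 * (1 - (0.5 + abs(t) / (2 * sqrt(2 + t^2))))
}

# Naive O(n^3) agglomerative clustering via the Lance-Williams recurrence
# for ward.D2 (distances treated as Euclidean; update on squared distances).
# Returns merge heights (sorted) and the leaf partition at each step.
naive_ward_d2 <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  partitions <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA)
    best_val <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b) {
          v <- d2[active[a], active[b]]
          if (v < best_val - 1e-12) {
            best_val <- v
            best <- c(a, b)
          }
        }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights[step] <- sqrt(best_val)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k != i && k != j) {
        nk <- sizes[k]
        d2[i, k] <- d2[k, i] <-
          ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
          (ni + nj + nk)
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    partitions[[step]] <- lapply(active, function(k) sort(members[[k]]))
  }
  list(heights = sort(heights), partitions = partitions)
}

# partition of leaves after each hclust merge, as sorted member sets
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  lapply(seq_len(n - 1L), function(step)
    unname(split(seq_len(n), stats::cutree(hc, k = n - step))))
}

canonical_partition <- function(p) {
  sets <- lapply(p, function(s) paste(sort(unlist(s)), collapse = ","))
  sort(unlist(sets))
}

# a vector of n positive values with exactly the requested mean and %CV
vector_with_cv <- function(n, mean, cv_pct) {
  z <- as.numeric(scale(seq_len(n)))     # mean 0, sd 1 exactly
  mean * (1 + (cv_pct / 100) * z)
}

# tiny two-sample, two-species peak table with one ISTD per panel
toy_peak_table <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    species = rep(c("PC 34:1", "PC 36:2", "ISTD PC"), 2),
    panel = "PL_CE_DG",
    area = c(2000, 500, 1000, 3000, 250, 1000),
    is_istd = rep(c(FALSE, FALSE, TRUE), 2)
  )
}

toy_istd_map <- function() {
  tibble::tibble(species = c("PC 34:1", "PC 36:2"),
                 istd_id = "ISTD PC", istd_conc = 1.0)
}

# a small low-noise simulation config used when the QC rules themselves are
# under test (benign technical CVs so planted failures are the only
# exclusions)
benign_qc_config <- function(seed = 1L) {
  planted <- planted_qc_failures()
  overrides <- planted$species[planted$failure == "override"]
  simulation_config(
    seed = seed,
    planted = planted,
    pqc_cv_overrides = dplyr::bind_rows(
      tibble::tibble(group = "tetracosactide", species = overrides,
                     cv_pct = c(27.8, 30.1)),
      tibble::tibble(group = "prednisolone", species = overrides,
                     cv_pct = c(7.3, 10.9))),
    technical_cv_pct = c(PL_CE_DG = 5, SPHINGO = 6, S1P = 6, TG = 8)
  )
}
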