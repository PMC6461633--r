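mv_fixture <- function(n = 5, p = 4, seed = 31) {
  withr::local_seed(seed, .local_envir = parent.frame())
  matrix(rlnorm(n * p, log(10), 0.5), nrow = n,
         dimnames = list(paste0("s", seq_len(n)),
                         c("PC 34:1", "PC 36:2", "PI 38:4", "SM 34:1")[seq_len(p)]))
}

test_that("abundance PCA matches a brute-force eigendecomposition", {
  mat <- mv_fixture()
  res <- pca_abundance(mat)
  X <- scale(log2(mat))
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  k <- min(nrow(mat) - 1, ncol(mat))
  scores_oracle <- X %*% ev$vectors[, seq_len(k)]
  for (j in seq_len(k)) {
    # align oracle sign to the package's deterministic convention
    s <- sign(ev$vectors[which.max(abs(ev$vectors[, j])), j])
    expect_equal(res$scores[, j], scores_oracle[, j] * s,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(100 * ev$values[seq_len(k)] / sum(ev$values),
               res$variance_explained, tolerance = 1e-8)
  expect_equal(sum(res$variance_explained), 100, tolerance = 1e-8)
  # scores are orthogonal
  cp <- crossprod(res$scores)
  expect_equal(cp[upper.tri(cp)], rep(0, sum(upper.tri(cp))),
               tolerance = 1e-8)
})

test_that("rank-1 structure loads entirely on PC1", {
  prof_a <- c(1, 2, 4, 8)
  prof_b <- c(8, 4, 2, 1)
  mat <- rbind(a1 = prof_a, a2 = prof_a, a3 = prof_a,
               b1 = prof_b, b2 = prof_b, b3 = prof_b)
  colnames(mat) <- c("PC 34:1", "PC 36:2", "PI 38:4", "SM 34:1")
  res <- pca_abundance(mat)
  expect_equal(res$variance_explained[1], 100, tolerance = 1e-8)
  expect_lt(res$variance_explained[2], 1e-8)
  expect_gt(abs(mean(res$scores[1:3, 1]) - mean(res$scores[4:6, 1])), 1)
})

test_that("PCA input validation catches degenerate inputs", {
  mat <- mv_fixture()
  mat[, 2] <- 5
  expect_error(pca_abundance(mat), "PC 36:2")
  expect_error(pca_abundance(mv_fixture()[1:2, ]), "3 samples")
  fc_const <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4,
                     dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  fc_const[] <- 1
  expect_error(pca_log2fc(fc_const), "zero total variance")
})

test_that("fold-change PCA separates simulated treatment signatures", {
  withr::local_seed(9)
  n_sp <- 30
  species <- paste0("PC 3", rep(2:7, 5), ":", rep(0:4, 6))[1:n_sp]
  sig_a <- rnorm(n_sp, 0, 1)
  sig_b <- -sig_a
  fc <- rbind(
    t(replicate(8, sig_a + rnorm(n_sp, 0, 0.3))),
    t(replicate(6, sig_b + rnorm(n_sp, 0, 0.3))))
  rownames(fc) <- c(paste0("P", 1:8), paste0("T", 1:6))
  colnames(fc) <- make.unique(species)
  res <- pca_log2fc(fc)
  pc1 <- res$scores[, 1]
  grp <- rep(c("A", "B"), c(8, 6))
  # silhouette of the two groups on PC1 is positive
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[grp == grp[i]][-match(i, which(grp == grp[i]))]))
    oth <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_true(max(pc1[grp == "A"]) < min(pc1[grp == "B"]) ||
                max(pc1[grp == "B"]) < min(pc1[grp == "A"]))
})

test_that("flipping one species' fold changes flips only its loading", {
  withr::local_seed(21)
  fc <- matrix(rnorm(8 * 5), nrow = 8,
               dimnames = list(paste0("s", 1:8), paste0("sp", 1:5)))
  res <- pca_log2fc(fc)
  fc2 <- fc
  # pick a species that does not carry the max |loading| on any component
  maxed <- apply(abs(res$loadings), 2, which.max)
  j <- setdiff(seq_len(5), maxed)[1]
  fc2[, j] <- -fc2[, j]
  res2 <- pca_log2fc(fc2)
  expect_equal(res2$loadings[j, ], -res$loadings[j, ], tolerance = 1e-8)
  expect_equal(res2$loadings[-j, ], res$loadings[-j, ], tolerance = 1e-8)
})

test_that("Pearson distances behave at the extremes and cluster first", {
  mat <- rbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 6, 8), s3 = c(9, 1, 7, 2))
  d <- pearson_dist(mat)
  expect_equal(as.matrix(d)["s1", "s2"], 0, tolerance = 1e-12)
  anti <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.matrix(pearson_dist(anti))["a", "b"], 2)

  # identical samples merge first in the heatmap clustering
  conc <- rbind(s1 = c(1, 2, 3, 4), s2 = c(1, 2, 3, 4), s3 = c(9, 1, 7, 2))
  colnames(conc) <- paste0("sp", 1:4)
  cl <- cluster_heatmap(conc)
  first <- cl$sample_hclust$merge[1, ]
  expect_setequal(-first, c(1, 2))
  expect_equal(cl$sample_hclust$height[1], 0, tolerance = 1e-12)
})

test_that("Pearson distance is invariant to positive affine row transforms", {
  withr::local_seed(4)
  mat <- matrix(rnorm(5 * 6), nrow = 5)
  slope <- runif(5, 0.5, 3)
  shift <- rnorm(5)
  mat2 <- mat * slope + shift
  expect_equal(as.numeric(pearson_dist(mat)), as.numeric(pearson_dist(mat2)),
               tolerance = 1e-12)
})

test_that("agglomeration matches the naive Lance-Williams oracle", {
  withr::local_seed(55)
  for (rep in 1:5) {
    mat <- matrix(rlnorm(6 * 8, log(10), 0.6), nrow = 6,
                  dimnames = list(paste0("s", 1:6), paste0("sp", 1:8)))
    cl <- cluster_heatmap(mat)
    d <- pearson_dist(t(cl$autoscaled))
    oracle <- naive_ward_d2(d)
    expect_equal(sort(cl$sample_hclust$height), oracle$heights,
                 tolerance = 1e-9)
    got <- hclust_partitions(cl$sample_hclust)
    for (step in seq_along(oracle$partitions)) {
      expect_equal(canonical_partition(got[[step]]),
                   canonical_partition(oracle$partitions[[step]]))
    }
  }
})

test_that("autoscaled rows are exact z-scores and ward variants differ", {
  mat <- mv_fixture(n = 6)
  cl <- cluster_heatmap(mat)
  expect_equal(unname(rowMeans(cl$autoscaled)), rep(0, nrow(cl$autoscaled)),
               tolerance = 1e-12)
  expect_equal(unname(apply(cl$autoscaled, 1, sd)),
               rep(1, nrow(cl$autoscaled)), tolerance = 1e-12)
  expect_setequal(cl$species_hclust$labels, colnames(mat))
  cl_d <- cluster_heatmap(mat, ward = "ward.D")
  expect_equal(cl_d$linkage, "ward.D")
  mat_bad <- mat
  mat_bad[, 1] <- 3
  expect_error(cluster_heatmap(mat_bad), "zero-variance")
})
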