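test_that("median normalization equalizes sample medians, preserving scale", {
  set.seed(8)
  m <- matrix(rlnorm(200), 20, 10)
  dimnames(m) <- list(paste0("r", 1:20), paste0("s", 1:10))
  norm <- normalizeMedian(m)
  meds <- apply(norm, 2, median)
  expect_equal(unname(meds), rep(meds[[1]], 10))
  # a global per-sample factor is removed exactly (up to the overall
  # rescale shared by every column through the median of medians)
  m2 <- m
  m2[, 3] <- m2[, 3] * 2
  norm2 <- normalizeMedian(m2)
  expect_equal(norm2[, 3] / norm2[, 1], norm[, 3] / norm[, 1])
  expect_equal(unname(apply(norm2, 2, median)),
               rep(median(norm2[, 1]), 10))
  # matrices with equal medians already pass through unchanged
  eq <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  dimnames(eq) <- list(paste0("r", 1:3), paste0("s", 1:4))
  expect_equal(normalizeMedian(eq), eq)
  expect_error(normalizeMedian(cbind(eq, s5 = c(0, 0, 0))),
               class = "lipidflow_zero_median")
})

test_that("autoscale gives unit sd, Pareto variance equals original sd", {
  set.seed(9)
  m <- matrix(rlnorm(80, 1, 0.8), 8, 10)
  dimnames(m) <- list(paste0("r", 1:8), paste0("s", 1:10))
  a <- scaleFeatures(m, "autoscale")
  expect_equal(unname(apply(a, 1, sd)), rep(1, 8))
  expect_equal(unname(rowMeans(a)), rep(0, 8))
  p <- scaleFeatures(m, "pareto")
  expect_equal(unname(apply(p, 1, var)), unname(apply(m, 1, sd)))
  const <- rbind(m, k = rep(2, 10))
  out <- scaleFeatures(const, "autoscale")
  expect_equal(unname(out["k", ]), rep(0, 10))
  expect_identical(attr(out, "constantRows"), "k")
})

test_that("PCA matches an independent eigendecomposition oracle", {
  set.seed(10)
  m <- matrix(rnorm(160), 20, 8)       # 20 items x 8 samples
  dimnames(m) <- list(paste0("r", 1:20), paste0("s", 1:8))
  scl <- scaleFeatures(m, "none")      # centered only
  pca <- lipidPCA(scl)
  # oracle: eigenvalues of the item-item scatter via covariance of samples
  X <- t(scl)
  ev <- eigen(crossprod(X), symmetric = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  expect_equal(pca$explainedVariance, ev / sum(ev), tolerance = 1e-8)
  # loadings orthonormal, explained fractions non-increasing, sum <= 1
  G <- crossprod(pca$loadings)
  expect_equal(G, diag(ncol(G)), ignore_attr = TRUE)
  expect_true(all(diff(pca$explainedVariance) <= 1e-12))
  expect_lte(sum(pca$explainedVariance), 1 + 1e-12)
  # reconstruction with all components reproduces the scaled matrix
  rec <- pca$scores %*% t(pca$loadings)
  expect_equal(rec, X, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a single separating variable puts 100% of variance on PC1", {
  m <- matrix(0, 3, 6,
              dimnames = list(paste0("r", 1:3), paste0("s", 1:6)))
  m[1, ] <- c(1, 1, 1, 5, 5, 5)
  pca <- lipidPCA(scaleFeatures(m, "none"))
  expect_equal(pca$explainedVariance[1], 1)
})

test_that("explained variance is invariant to sample order and sign fixed", {
  set.seed(12)
  m <- matrix(rnorm(60), 10, 6)
  dimnames(m) <- list(paste0("r", 1:10), paste0("s", 1:6))
  p1 <- lipidPCA(scaleFeatures(m, "pareto"))
  perm <- sample(6)
  p2 <- lipidPCA(scaleFeatures(m[, perm], "pareto"))
  expect_equal(p1$explainedVariance, p2$explainedVariance)
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(p1$loadings)))
    expect_gt(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
  expect_equal(p2$loadings, p1$loadings)
})

test_that("confidence ellipses follow the chi-squared quantile rule", {
  set.seed(13)
  s <- matrix(rnorm(40), 20, 2)
  e <- confidenceEllipse(s)
  expect_equal(e$center, colMeans(s))
  # equivariance: scaling axis 1 by 3 scales that semi-axis by 3
  s3 <- s %*% diag(c(3, 1))
  e3 <- confidenceEllipse(s3)
  # isotropic-free check via the covariance eigenvalues themselves
  expect_equal(sort(e3$radii^2 / qchisq(0.95, 2)),
               sort(eigen(cov(s3))$values), tolerance = 1e-10)
  # exact circle for exactly isotropic scores
  iso <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  ei <- confidenceEllipse(iso)
  expect_equal(ei$radii[1], ei$radii[2])
  expect_error(confidenceEllipse(s[1:2, ]),
               class = "lipidflow_too_few_samples")
})

test_that("the 95% ellipse covers about 95% of bivariate normal points", {
  set.seed(14)
  n <- 4000
  pts <- cbind(rnorm(n, 0, 2), rnorm(n) + 0.5)
  e <- confidenceEllipse(pts, level = 0.95)
  inside <- mahalanobis(pts, colMeans(pts), cov(pts)) <= qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.02)
})

test_that("heatmap selection is deterministic top-k by p with fixed ties", {
  set.seed(15)
  base <- matrix(rlnorm(40 * 9, 0, 0.2), 40, 9)
  rownames(base) <- replicate(40, formatLipidName(randomSpecies()))
  while (anyDuplicated(rownames(base)))
    rownames(base)[duplicated(rownames(base))] <-
      replicate(sum(duplicated(rownames(base))),
                formatLipidName(randomSpecies()))
  colnames(base) <- paste0("s", 1:9)
  g <- rep(c("WT", "HOM"), c(5, 4))
  base[1:10, g == "HOM"] <- base[1:10, g == "HOM"] * 8  # planted species
  hm <- heatmapSelectCluster(base, g, k = 20)
  expect_length(hm$items, 20)
  expect_true(all(rownames(base)[1:10] %in% hm$items))
  hm2 <- heatmapSelectCluster(base, g, k = 20)
  expect_identical(hm$items, hm2$items)
  expect_identical(hm$rowOrder, hm2$rowOrder)
  # k larger than the item count clamps with a message
  expect_message(hmAll <- heatmapSelectCluster(base, g, k = 100),
                 "clamped")
  expect_length(hmAll$items, 40)
})

test_that("sample dendrogram matches a hand-worked complete-linkage trace", {
  # one informative row places the 4 samples at 1-D positions 0, 1, 4, 10
  # (the second row is constant and standardizes to zero); after
  # autoscaling, positions are divided by sd(0,1,4,10). Complete linkage:
  # (s1,s2) merge at 1, s3 joins at max(4,3)=4, s4 at max(10,9,6)=10.
  m <- rbind(a = c(0, 1, 4, 10), b = rep(1, 4))
  rownames(m) <- c("PC 16:0_18:1", "PE 18:0_20:4")
  colnames(m) <- paste0("s", 1:4)
  hm <- heatmapSelectCluster(m, rep(c("WT", "HOM"), each = 2), k = 2)
  hc <- hm$colDendrogram
  expect_equal(hc$height, c(1, 4, 10) / sd(c(0, 1, 4, 10)))
  expect_equal(hc$merge[1, ], c(-1, -2))
  expect_equal(hc$merge[2, ], c(-3, 1))
  expect_equal(hc$merge[3, ], c(-4, 2))
})
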