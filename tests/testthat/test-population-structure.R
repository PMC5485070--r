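test_that("marker PCA matches the eigendecomposition oracle", {
  g <- randomGenotypes(6, 20, seed = 8)
  pca <- pcaMarkers(g, 5)
  poly <- minorAlleleFrequency(g) > 0
  Z <- scale(callMatrix(g)[, poly, drop = FALSE])
  C <- tcrossprod(Z) / (nrow(Z) - 1)      # n x n form, same spectrum
  eg <- eigen(C, symmetric = TRUE)
  for (j in 1:5) {
    sc <- pca$scores[, j]
    ev <- eg$vectors[, j] * sqrt(eg$values[j] * (nrow(Z) - 1))
    expect_lt(min(max(abs(sc - ev)), max(abs(sc + ev))), 1e-8)
  }
  expect_equal(pca$explained_fraction, eg$values[1:5] / ncol(Z),
               tolerance = 1e-8)
  # explained fractions: non-negative, non-increasing, sum <= 1
  expect_true(all(pca$explained_fraction >= 0))
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
  expect_lte(sum(pca$explained_fraction), 1 + 1e-9)
})

test_that("duplicated accession pairs coincide on the PC scores", {
  set.seed(10)
  half <- matrix(rbinom(3 * 30, 1, 0.4), 3, 30)
  calls <- rbind(half, half)
  rownames(calls) <- paste0("a", 1:6)
  g <- GenotypeMatrix(calls, rep("1", 30), seq_len(30) * 50L)
  pca <- pcaMarkers(g, 2)
  for (i in 1:3)
    expect_lt(abs(pca$scores[i, 1] - pca$scores[i + 3, 1]), 1e-10)
})

test_that("spatial weight rows are standardized and schemes behave", {
  geo <- gridGeo(20, seed = 2)
  for (scheme in c("knn", "gabriel")) {
    w <- buildSpatialWeights(geo, scheme, k = 3)
    rs <- rowSums(w$W)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
    expect_true(all(diag(w$W) == 0))      # no self-neighbours
  }

  # 3 collinear equidistant points, knn k = 1: middle point receives an
  # incoming edge from both ends; union-symmetrization makes all pairs
  # adjacent to the middle
  geo3 <- data.frame(accession_id = c("p1", "p2", "p3"),
                     latitude = c(0, 0, 0), longitude = c(0, 1, 2),
                     elevation = 0)
  w3 <- suppressMessages(buildSpatialWeights(geo3, "knn", k = 1,
                                             style = "B"))
  expect_equal(unname(w3$W[, 2]), c(1, 0, 1))   # both ends point inward
  expect_equal(sum(w3$W), 4)                    # 2 directed + symmetrized

  # unit square: Gabriel graph keeps the 4 sides, no diagonals
  sq <- data.frame(accession_id = paste0("c", 1:4),
                   latitude = c(0, 0, 1, 1), longitude = c(0, 1, 0, 1),
                   elevation = 0)
  wsq <- buildSpatialWeights(sq, "gabriel", style = "B")
  expect_equal(sum(wsq$W) / 2, 4)
  expect_equal(wsq$W[1, 4], 0)            # diagonal absent
  expect_equal(wsq$W[2, 3], 0)
})

test_that("Moran's I equals the double-sum oracle and handles errors", {
  geo <- gridGeo(15, seed = 3)
  w <- buildSpatialWeights(geo, "knn", k = 3)
  set.seed(4)
  x <- rnorm(15)
  m <- moransI(x, w)
  expect_equal(m$statistic, moranOracle(x, w$W), tolerance = 1e-12)
  expect_equal(m$expectation, -1 / 14)

  # 4-point rook lattice with values (1,2,2,1)
  W4 <- rbind(c(0, 1, 1, 0), c(1, 0, 0, 1), c(1, 0, 0, 1),
              c(0, 1, 1, 0))
  w4 <- list(W = W4)
  class(w4) <- "stresshap_listw"
  v <- c(1, 2, 2, 1)
  expect_equal(moransI(v, w4)$statistic, moranOracle(v, W4),
               tolerance = 1e-12)

  expect_error(moransI(rep(1, 15), w), "constant")
})

test_that("Moran's I statistic agrees with the ape implementation", {
  skip_if_not_installed("ape")
  geo <- gridGeo(25, seed = 5)
  w <- buildSpatialWeights(geo, "knn", k = 4)
  set.seed(6)
  x <- rnorm(25)
  ours <- moransI(x, w)
  theirs <- ape::Moran.I(x, w$W)
  expect_equal(ours$statistic, theirs$observed, tolerance = 1e-10)
  expect_equal(ours$expectation, theirs$expected, tolerance = 1e-12)
  expect_equal(ours$sd, theirs$sd, tolerance = 1e-8)
})

test_that("permutation p-value is seed-deterministic and detects signal", {
  set.seed(7)
  geo <- data.frame(accession_id = sprintf("a%02d", 1:50),
                    latitude = rep(0, 50) + rnorm(50, 0, 1e-4),
                    longitude = seq_len(50), elevation = 0)
  w <- buildSpatialWeights(geo, "knn", k = 2)
  x <- geo$longitude + rnorm(50, 0, 2)    # autocorrelated along the line
  m1 <- moransI(x, w, method = "permutation", n_perm = 999, seed = 1)
  m2 <- moransI(x, w, method = "permutation", n_perm = 999, seed = 1)
  expect_identical(m1$p_value, m2$p_value)
  expect_gt(m1$statistic, 0)
  expect_lt(m1$p_value, 0.05)
})

test_that("analytic expectation matches permutation mean", {
  geo <- gridGeo(12, seed = 8)
  w <- buildSpatialWeights(geo, "knn", k = 3)
  set.seed(9)
  x <- rnorm(12)
  m <- moransI(x, w, method = "permutation", n_perm = 10000, seed = 2)
  I_perm <- withr::with_seed(2, replicate(10000, {
    xs <- sample(x)
    moranOracle(xs, w$W)
  }))
  se <- sd(I_perm) / sqrt(10000)
  expect_lt(abs(mean(I_perm) - m$expectation), 3 * se + 0.01)
})

test_that("informative-PC selection follows the prefix rule", {
  n <- 40
  geo <- gridGeo(n, seed = 10)
  w <- buildSpatialWeights(geo, "knn", k = 5)
  # construct PC-like scores: 1-2 spatial (copies of coordinates),
  # 3 random, 4 spatial again
  set.seed(11)
  scores <- cbind(geo$longitude, geo$latitude, rnorm(n),
                  geo$longitude + rnorm(n, 0, 0.1))
  pca <- structure(list(scores = scores,
                        explained_fraction = c(0.4, 0.3, 0.2, 0.1)),
                   class = "stresshap_pca")
  sel <- selectInformativePcs(pca, w, alpha = 0.001)
  expect_identical(sel$retained, 1:2)     # stops at the first failure
  expect_identical(sel$rule, "prefix")
  sel_any <- selectInformativePcs(pca, w, alpha = 0.001, rule = "any")
  expect_true(4 %in% sel_any$retained && !(3 %in% sel_any$retained))

  # spatially random scores: empty retained set
  set.seed(12)
  null_pca <- structure(list(scores = matrix(rnorm(n * 3), n),
                             explained_fraction = c(0.4, 0.3, 0.3)),
                        class = "stresshap_pca")
  expect_length(selectInformativePcs(null_pca, w, alpha = 0.001)$retained,
                0)

  # determinism
  s1 <- selectInformativePcs(pca, w, method = "permutation", seed = 3)
  s2 <- selectInformativePcs(pca, w, method = "permutation", seed = 3)
  expect_identical(s1$p_values, s2$p_values)
})

test_that("Ward clustering matches the exhaustive oracle for n <= 8", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 3), 8, 3,
                dimnames = list(paste0("a", 1:8), NULL))
    oracle <- wardOracle(X)
    for (k in c(2, 4, 6)) {
      ours <- wardCluster(X, k)
      memb <- oracle$partitions[[8 - k]]
      expect_identical(canonicalPartition(unname(ours$assignment)),
                       canonicalPartition(memb))
    }
    # Ward objective: total within-cluster SS non-decreasing over merges
    expect_true(all(diff(oracle$ess) >= -1e-10))
    # and the hclust heights are monotone
    expect_true(all(diff(wardCluster(X, 2)$height) >= -1e-10))
  }
})

test_that("Ward cut recovers separated blobs and handles edge cuts", {
  set.seed(13)
  X <- rbind(matrix(rnorm(20 * 2, 0, 0.3), 20),
             matrix(rnorm(20 * 2, 8, 0.3), 20))
  rownames(X) <- paste0("a", 1:40)
  g <- wardCluster(X, 2)
  expect_identical(unname(g$assignment[1:20]), rep(1L, 20))
  expect_identical(unname(g$assignment[21:40]), rep(2L, 20))

  gn <- wardCluster(X, 40)
  expect_length(unique(gn$assignment), 40)
  expect_error(wardCluster(X, 0), "n_groups")
})

test_that("cluster ANOVA calibrates under the null and detects shifts", {
  set.seed(14)
  n <- 80
  ids <- sprintf("a%03d", 1:n)
  groups <- list(assignment = setNames(sample(rep(1:4, each = n / 4)), ids))
  lc <- setNames(sample(c("winter", "summer"), n, replace = TRUE), ids)

  # null: p-values approximately uniform
  nrep <- 1000
  pv <- replicate(nrep, {
    resp <- data.frame(accession_id = ids, trait = rnorm(n))
    clusterPhenotypeAnova(resp, groups, lc)$p_value
  })
  frac <- mean(pv < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)

  # planted group shift of 2 SD
  resp <- data.frame(accession_id = ids,
                     trait = rnorm(n) + 2 * (groups$assignment[ids] == 1))
  expect_lt(clusterPhenotypeAnova(resp, groups, lc)$p_value, 1e-3)

  # singleton group is refused with advice
  g1 <- groups
  g1$assignment[1] <- 9L
  expect_error(clusterPhenotypeAnova(resp, g1, lc), "n_groups")
})
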