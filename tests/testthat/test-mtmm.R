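test_that("composite trait vectors follow the PC1 definitions", {
  p <- smallPanel()
  tv <- buildTraitVectors(p$ph$responses_true)
  expect_equal(unname(sd(tv$p1)), 1, tolerance = 1e-10)
  expect_equal(unname(sd(tv$p2)), 1, tolerance = 1e-10)
  expect_identical(names(tv$p1), names(tv$p2))
  # sign convention: positively correlated with the group mean
  resp <- p$ph$responses_true
  Z1 <- scale(as.matrix(resp[c("P_rapae", "P_xylostella",
                               "Drought_Pieris", "Botrytis_Pieris")]))
  expect_gt(cor(tv$p1, rowMeans(Z1)), 0)

  # four perfectly correlated columns -> PC1 explains everything
  base <- resp
  v <- rnorm(nrow(base))
  base$P_rapae <- v; base$P_xylostella <- 2 * v + 1
  base$Drought_Pieris <- -3 * v; base$Botrytis_Pieris <- 0.5 * v
  expect_equal(buildTraitVectors(base)$explained_fraction_p1, 1,
               tolerance = 1e-10)

  expect_error(buildTraitVectors(resp[1:2, ]), "3 complete")
  expect_error(buildTraitVectors(resp[, -2]), "lack columns")
})

test_that("independent columns give explained fraction near 1/4", {
  set.seed(30)
  n <- 2000
  resp <- data.frame(accession_id = sprintf("a%04d", 1:n))
  for (tr in c("Drought", "P_rapae", "Drought_Pieris", "Botrytis_Pieris",
               "P_xylostella", "F_occidentalis", "M_persicae"))
    resp[[tr]] <- rnorm(n)
  tv <- buildTraitVectors(resp)
  expect_lt(abs(tv$explained_fraction_p1 - 0.25), 0.05)
  expect_lt(abs(tv$explained_fraction_p2 - 1 / 3), 0.05)
})

test_that("MTMM variance components: duplicated trait and recovery", {
  p <- smallPanel()
  tv <- buildTraitVectors(p$ph$responses_true)
  fit_dup <- suppressWarnings(fitMtmmVarcomp(tv$p1, tv$p1, p$K))
  cg <- cov2cor(fit_dup$Vg)[1, 2]
  ce <- cov2cor(fit_dup$Ve)[1, 2]
  expect_gte(cg, 0.99)
  expect_gte(ce, 0.99)

  # recovery of a planted genetic correlation of 0.5
  g <- randomGenotypes(150, 800, seed = 41)
  K <- computeKinship(g)
  eg <- eigen(kinship(K), symmetric = TRUE)
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  rg <- vapply(1:5, function(s) {
    set.seed(500 + s)
    G <- L %*% matrix(rnorm(150 * 2), 150, 2) %*%
      chol(matrix(c(1, .5, .5, 1), 2))
    y1 <- setNames(G[, 1] + rnorm(150), accessionIds(g))
    y2 <- setNames(G[, 2] + rnorm(150), accessionIds(g))
    cov2cor(fitMtmmVarcomp(y1, y2, K)$Vg)[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(rg) - 0.5), 0.15)
})

test_that("identity kinship flags non-identifiability", {
  n <- 40
  ids <- sprintf("a%02d", 1:n)
  K <- new("KinshipMatrix", K = `dimnames<-`(diag(n), list(ids, ids)),
           estimator = "standardized", ridge = 0)
  set.seed(42)
  y1 <- setNames(rnorm(n), ids); y2 <- setNames(rnorm(n), ids)
  expect_warning(fit <- fitMtmmVarcomp(y1, y2, K), "identified")
  expect_false(fit$identifiable)
  # only the sum Vg + Ve is identified: it must match the bivariate
  # sample covariance (REML), not each matrix separately
  S <- cov(cbind(y1, y2))
  expect_equal(unname(fit$Vg + fit$Ve), unname(S), tolerance = 0.05)
})

test_that("GLS F tests reduce to the stacked-OLS oracle under identity", {
  set.seed(43)
  g <- randomGenotypes(30, 25, seed = 44)
  ids <- accessionIds(g)
  p1 <- setNames(rnorm(30), ids)
  p2 <- setNames(rnorm(30), ids)
  for (s2 in c(1, 4)) {                   # invariant to the overall scale
    plug <- list(Vg = matrix(0, 2, 2), Ve = diag(2) * s2)
    res <- glsFTests(g, plug, p1, p2, maf_min = 0.05)
    X <- callMatrix(g)[, res$marker, drop = FALSE]
    for (j in seq_len(nrow(res))) {
      o <- stackedOlsF(p1, p2, X[, j])
      expect_equal(res$p_full[j], o$p_full, tolerance = 1e-8)
      expect_equal(res$p_common[j], o$p_common, tolerance = 1e-8)
      expect_equal(res$p_specific[j], o$p_specific, tolerance = 1e-8)
    }
  }
})

test_that("common effects hit the common test, specific the specific", {
  set.seed(45)
  n <- 120
  g <- randomGenotypes(n, 60, seed = 46)
  ids <- accessionIds(g)
  X <- callMatrix(g)
  wins_common <- wins_specific <- logical(10)
  for (s in 1:10) {
    set.seed(600 + s)
    xc <- X[, 2 * s - 1]; xs <- X[, 2 * s]
    base1 <- rnorm(n); base2 <- rnorm(n)
    p1c <- setNames(base1 + 1.2 * xc, ids)  # equal effect on both traits
    p2c <- setNames(base2 + 1.2 * xc, ids)
    plug <- list(Vg = matrix(0, 2, 2), Ve = diag(2))
    rc <- glsFTests(g, plug, p1c, p2c, maf_min = 0)
    i <- match(colnames(X)[2 * s - 1], rc$marker)
    wins_common[s] <- rc$p_common[i] < rc$p_specific[i]
    p1s <- setNames(base1 + 1.5 * xs, ids)  # trait-1-only effect
    p2s <- setNames(base2, ids)
    rs <- glsFTests(g, plug, p1s, p2s, maf_min = 0)
    i <- match(colnames(X)[2 * s], rs$marker)
    wins_specific[s] <- rs$p_specific[i] < 1e-3
  }
  expect_gte(sum(wins_common), 9)
  expect_gte(sum(wins_specific), 9)
})

test_that("marker permutation leaves p-values unchanged", {
  p <- smallPanel()
  tv <- buildTraitVectors(p$ph$responses_true)
  fit <- fitMtmmVarcomp(tv$p1, tv$p2, p$K)
  res1 <- glsFTests(p$geno, fit, tv$p1, tv$p2)
  set.seed(47)
  perm <- sample(nMarkers(p$geno))
  mk <- markerInfo(p$geno)
  shuffled <- GenotypeMatrix(callMatrix(p$geno)[, perm],
                             as.character(GenomicRanges::seqnames(mk))[perm],
                             GenomicRanges::start(mk)[perm])
  res2 <- glsFTests(shuffled, fit, tv$p1, tv$p2)
  m <- merge(res1, res2, by = "marker")
  expect_equal(m$p_full.x, m$p_full.y, tolerance = 1e-12)
  expect_equal(m$p_specific.x, m$p_specific.y, tolerance = 1e-12)
})

test_that("QTL regions merge overlapping windows and floor at 1", {
  res <- data.frame(
    marker = c("m1", "m2", "m3", "m4"),
    chromosome = c("1", "1", "1", "2"),
    position = c(10000, 25000, 200000, 15000),
    maf = 0.2, beta = 0, alpha = 0,
    p_full = 1, p_common = 1,
    p_specific = c(1e-5, 1e-6, 1e-4, 0.5))
  reg <- selectQtlRegions(res, "specific", 4, 20000)
  # m1 and m2 windows overlap and merge; m3 is separate; m4 fails the
  # threshold
  expect_length(reg, 2)
  expect_equal(GenomicRanges::start(reg)[1], 1)      # floored
  expect_equal(GenomicRanges::end(reg)[1], 35000)
  expect_equal(S4Vectors::mcols(reg)$n_snps, c(2L, 1L))
  expect_equal(S4Vectors::mcols(reg)$peak_neg_log10[1], 6)

  # idempotent under input row order
  reg2 <- selectQtlRegions(res[c(3, 1, 4, 2), ], "specific", 4, 20000)
  expect_equal(GenomicRanges::start(reg), GenomicRanges::start(reg2))

  # nothing significant -> empty
  expect_length(selectQtlRegions(res, "specific", 10, 20000), 0)
})

test_that("LD r2 matches direct correlation arithmetic", {
  calls <- rbind(a1 = c(0, 0, 1, 0), a2 = c(0, 1, 1, 1),
                 a3 = c(1, 0, 0, 0), a4 = c(1, 1, 0, 1),
                 a5 = c(0, 0, 1, 0), a6 = c(1, 1, 0, 1))
  g <- GenotypeMatrix(calls, rep("1", 4),
                      c(1000L, 5000L, 9000L, 60000L))
  ld <- ldR2(g, "m1", window_bp = 10000)
  expect_identical(ld$marker, c("m1", "m2", "m3"))   # m4 out of window
  expect_equal(ld$r2[1], 1)                          # self
  expect_equal(ld$r2[3], 1)                          # complement: |r| = 1
  expect_equal(ld$r2[2], cor(calls[, 1], calls[, 2])^2, tolerance = 1e-12)

  # monomorphic companion -> NA
  calls2 <- cbind(calls[, 1:2], c(1, 1, 1, 1, 1, 1))
  colnames(calls2) <- c("m1", "m2", "m5")
  g2 <- GenotypeMatrix(calls2, rep("1", 3), c(1000L, 5000L, 7000L))
  ld2 <- ldR2(g2, "m1", window_bp = 10000)
  expect_true(is.na(ld2$r2[ld2$marker == "m5"]))
  expect_error(ldR2(g, "nope"), "not found")
})
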