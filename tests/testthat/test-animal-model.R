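shortMcmc <- function(n_iter = 6000, thin = 5, burn_in = 1000, seed = 1)
  mcmcSettings(n_iter, thin, burn_in, seed)

test_that("settings and priors validate their inputs", {
  expect_error(mcmcSettings(1000, 5, 2000), "burn_in")
  expect_error(mcmcSettings(1000, 0, 100), "thin")
  expect_error(priorSpec(V_g = -1), "V_g")
  pr <- thresholdPrior()
  expect_equal(pr$V_g, 0.002 / 2.002)
  expect_equal(pr$nu_g, 2.002)
})

test_that("chains are bit-identical under a fixed seed", {
  p <- smallPanel()
  y <- setNames(p$ph$responses_true$Drought,
                p$ph$responses_true$accession_id)
  m1 <- fitGaussianAnimalModel(y, K = p$K, mcmc = shortMcmc(2000, 2, 500))
  m2 <- fitGaussianAnimalModel(y, K = p$K, mcmc = shortMcmc(2000, 2, 500))
  expect_identical(m1$samples$beta, m2$samples$beta)
  expect_identical(m1$samples$va, m2$samples$va)
  m3 <- fitGaussianAnimalModel(y, K = p$K,
                               mcmc = shortMcmc(2000, 2, 500, seed = 2))
  expect_false(identical(m1$samples$va, m3$samples$va))
})

test_that("with an identity kinship the intercept tracks the sample mean", {
  n <- 200
  ids <- sprintf("a%03d", 1:n)
  K <- new("KinshipMatrix",
           K = `dimnames<-`(diag(n), list(ids, ids)),
           estimator = "standardized", ridge = 0)
  set.seed(5)
  y <- setNames(rnorm(n), ids)
  fit <- fitGaussianAnimalModel(y, K = K, mcmc = shortMcmc())
  expect_lt(abs(fit$fixed$PM[1] - mean(y)), 0.15)
})

test_that("residual variance posterior matches the conjugate closed form", {
  # pin the genetic variance at ~0 with an extreme prior so the model
  # reduces to y = mu + e; then ve | y is inverse-gamma with shape
  # (nu + n - 1)/2 and rate (nu V + sum((y - ybar)^2))/2 after
  # marginalizing the flat-prior intercept
  p <- smallPanel()
  ids <- accessionIds(p$K)
  n <- length(ids)
  set.seed(6)
  y <- setNames(rnorm(n, 5, 2), ids)
  nu_e <- 0.002; V_e <- 1
  pr <- priorSpec(V_g = 1e-12, nu_g = 1e6, V_e = V_e, nu_e = nu_e)
  fit <- fitGaussianAnimalModel(y, K = p$K, prior = pr,
                                mcmc = mcmcSettings(11000, 5, 1000,
                                                    seed = 3))
  draws <- fit$samples$ve
  expect_length(draws, 2000)
  S <- sum((y - mean(y))^2)
  cdf <- function(x) stats::pgamma(1 / x, shape = (nu_e + n - 1) / 2,
                                   rate = (nu_e * V_e + S) / 2,
                                   lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(draws, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted life-cycle effect is recovered with small pMCMC", {
  set.seed(7)
  g <- randomGenotypes(250, 1200, seed = 31)
  K <- computeKinship(g)
  ids <- accessionIds(g)
  n <- length(ids)
  eg <- eigen(kinship(K), symmetric = TRUE)
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  h2 <- 0.4; total <- 100
  gval <- drop(L %*% rnorm(n)) * sqrt(h2 * total)
  winter <- rbinom(n, 1, 0.3)
  y <- setNames(20 - 9 * winter + gval +
                  rnorm(n, 0, sqrt((1 - h2) * total)), ids)
  X <- cbind(life_cycle_winter = winter)
  rownames(X) <- ids
  fit <- fitGaussianAnimalModel(y, X, K,
                                mcmc = mcmcSettings(15000, 10, 3000,
                                                    seed = 4))
  row <- fit$fixed[fit$fixed$term == "life_cycle_winter", ]
  psd <- sd(fit$samples$beta[, "life_cycle_winter"])
  expect_lt(abs(row$PM - (-9)), 2 * psd)
  expect_lt(row$pMCMC, 0.01)
  # credible interval brackets the posterior mean
  expect_true(row$lower <= row$PM && row$PM <= row$upper)
})

test_that("pMCMC is floored at 2 / retained samples and never zero", {
  p <- smallPanel()
  ids <- accessionIds(p$K)
  set.seed(8)
  x <- rnorm(60)
  y <- setNames(50 * x + rnorm(60), ids)   # overwhelming effect
  X <- cbind(x = x); rownames(X) <- ids
  fit <- fitGaussianAnimalModel(y, X, p$K, mcmc = shortMcmc(3000, 2, 1000))
  row <- fit$fixed[fit$fixed$term == "x", ]
  expect_identical(row$pMCMC, 2 / fit$retained)
  expect_gt(row$pMCMC, 0)
})

test_that("thinning at 50 keeps lag-1 autocorrelation below 0.1", {
  p <- smallPanel()
  y <- setNames(p$ph$responses_true$P_rapae,
                p$ph$responses_true$accession_id)
  fit <- fitGaussianAnimalModel(y, K = p$K,
                                mcmc = mcmcSettings(30000, 50, 5000,
                                                    seed = 9))
  expect_true(fit$autocorr_ok)
  expect_true(all(fit$fixed$lag1 < 0.1))
})

test_that("gaussian posterior mean of beta agrees with GLS under K = I", {
  n <- 150
  ids <- sprintf("a%03d", 1:n)
  K <- new("KinshipMatrix", K = `dimnames<-`(diag(n), list(ids, ids)),
           estimator = "standardized", ridge = 0)
  set.seed(10)
  x <- rnorm(n)
  y <- setNames(2 + 1.5 * x + rnorm(n), ids)
  X <- cbind(x = x); rownames(X) <- ids
  fit <- fitGaussianAnimalModel(y, X, K,
                                mcmc = mcmcSettings(20000, 5, 2000,
                                                    seed = 11))
  ols <- coef(lm(y ~ x))
  draws <- fit$samples$beta[, "x"]
  mc_se <- sd(draws) / sqrt(effectiveSizeForTest(draws))
  expect_lt(abs(mean(draws) - ols[2]), 3 * mc_se + 0.02)
})

test_that("threshold model recovers a planted latitude effect", {
  p <- smallPanel()
  ids <- accessionIds(p$K)
  set.seed(12)
  zlat <- drop(scale(p$geo$latitude))
  lab <- setNames(as.numeric(zlat * 2 + rnorm(60) > 0), ids)
  X <- cbind(latitude = zlat, elevation = rnorm(60))
  rownames(X) <- ids
  fit <- fitThresholdAnimalModel(lab, X, p$K,
                                 mcmc = shortMcmc(8000, 5, 2000))
  row <- fit$fixed[fit$fixed$term == "latitude", ]
  expect_gt(row$PM, 0)
  expect_lt(row$pMCMC, 0.01)
  # residual variance is fixed at 1
  expect_equal(unique(fit$samples$ve), 1)
})

test_that("threshold model is calibrated under the null", {
  # panel size in the study's range: pMCMC calibration is a
  # large-sample property of the probit animal model
  g <- randomGenotypes(200, 600, seed = 55)
  K <- computeKinship(g)
  ids <- accessionIds(g)
  ok <- vapply(1:20, function(s) {
    set.seed(400 + s)
    lab <- setNames(rbinom(200, 1, 0.4), ids)
    X <- cbind(elevation = rnorm(200), latitude = rnorm(200),
               longitude = rnorm(200))
    rownames(X) <- ids
    fit <- suppressWarnings(
      fitThresholdAnimalModel(lab, X, K,
                              mcmc = mcmcSettings(6000, 4, 1200,
                                                  seed = s)))
    cov_rows <- fit$fixed$term != "intercept"
    all(fit$fixed$pMCMC[cov_rows] > 0.05)
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("complete separation warns instead of failing", {
  p <- smallPanel()
  ids <- accessionIds(p$K)
  zlat <- drop(scale(p$geo$latitude))
  lab <- setNames(as.numeric(zlat > median(zlat)), ids)
  X <- cbind(latitude = zlat)
  rownames(X) <- ids
  expect_warning(
    fitThresholdAnimalModel(lab, X, p$K, mcmc = shortMcmc(500, 1, 100)),
    "separation")
})

test_that("trade-off models produce a summary per single stress", {
  p <- smallPanel()
  fits <- tradeOffModels(p$ph$responses_true, p$ph$life_cycle, p$K,
                         mcmc = shortMcmc(1500, 2, 300))
  expect_named(fits, c("Drought", "P_rapae", "P_xylostella",
                       "F_occidentalis", "M_persicae"))
  tab <- attr(fits, "table")
  # each model: intercept + 4 other stresses + life cycle
  expect_identical(nrow(tab), 5L * 6L)
  expect_true(all(tab$pMCMC > 0 & tab$pMCMC <= 1))
})
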