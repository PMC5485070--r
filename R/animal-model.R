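## Bayesian kinship ("animal") mixed models by Gibbs sampling.
##
## Gaussian model: y = X beta + g + e, g ~ N(0, va K), e ~ N(0, ve I),
## flat prior on beta, scaled inverse-gamma (V, nu) priors on the
## variance components (shape nu/2, rate nu V / 2).  One
## eigendecomposition of K turns the genetic-effect update into n
## independent draws in the rotated basis.
##
## Threshold (probit) model for a binary response: a latent liability
## l = X beta + g + e with e ~ N(0, 1) fixed for identifiability is
## augmented into the sampler; observed = 1 iff l > 0.

#' Variance-component prior specification
#'
#' @param V_g,nu_g scale and degree of belief for the genetic variance
#'   (defaults V = 1, nu = 0.002: the near-flat prior used for the
#'   Gaussian stress-response and trade-off models).
#' @param V_e,nu_e likewise for the residual variance (ignored by the
#'   threshold model, whose residual variance is fixed at 1).
#' @return list of class \code{"stresshap_prior"}.
#' @export
priorSpec <- function(V_g = 1, nu_g = 0.002, V_e = 1, nu_e = 0.002) {
  stopifnot(V_g > 0, nu_g > 0, V_e > 0, nu_e > 0)
  structure(list(V_g = V_g, nu_g = nu_g, V_e = V_e, nu_e = nu_e),
            class = "stresshap_prior")
}

#' Prior used for the binary life-cycle (threshold) model
#'
#' Scale V = 1 * (0.002 / 2.002), degree of belief nu = 2.002 on the
#' genetic component.
#' @return list of class \code{"stresshap_prior"}.
#' @export
thresholdPrior <- function() priorSpec(V_g = 0.002 / 2.002, nu_g = 2.002)

#' MCMC chain settings
#'
#' Defaults are the Gaussian-model settings (150,000 iterations, thin
#' 50, burn-in 50,000); the threshold model conventionally runs ten
#' times longer (\code{mcmcSettings(1500000, 500, 500000)}).
#'
#' @param n_iter total iterations; \code{thin} sampling interval;
#'   \code{burn_in} discarded initial iterations; \code{seed} RNG seed.
#' @param thin,burn_in,seed see above.
#' @return list of class \code{"stresshap_mcmc"}.
#' @export
mcmcSettings <- function(n_iter = 150000, thin = 50, burn_in = 50000,
                         seed = 42) {
  stopifnot(thin >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(n_iter = as.integer(n_iter), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "stresshap_mcmc")
}

## Core sampler shared by the Gaussian and threshold models.
##
## The genetic effects are collapsed out of the variance and
## fixed-effect updates (the marginal covariance is diagonal in the
## kinship eigenbasis, diag(va lam_i + ve)), which keeps the chain
## mixing fast where the classic single-site scheme stalls:
##   (a) beta | va, ve  ~ exact Gaussian GLS conditional,
##   (b) (log va[, log ve]) | beta ~ Metropolis-within-Gibbs on the
##       marginal likelihood times the scaled inverse-gamma (V, nu)
##       priors,
##   (c) threshold model only: genetic effects a | . conjugately, then
##       the latent liability by truncated-normal augmentation.
animalGibbs <- function(y, X, K, prior, mcmc, threshold = FALSE,
                        label = NULL) {
  n <- length(y)
  p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("K is not positive semi-definite; apply the ridge repair first")
  lam <- pmax(eg$values, 0)
  pos <- lam > 1e-12
  if (!any(pos)) stop("kinship matrix is singular with no usable eigenvalues")
  U <- eg$vectors
  Xs <- crossprod(U, X)
  npos <- sum(pos)

  keep_n <- length(seq(mcmc$burn_in + mcmc$thin, mcmc$n_iter,
                       by = mcmc$thin))
  beta_s <- matrix(NA_real_, keep_n, p, dimnames = list(NULL, colnames(X)))
  va_s <- numeric(keep_n); ve_s <- numeric(keep_n)

  ## log posterior of the variances given beta, genetic effects
  ## integrated out; scaled inverse-gamma priors (log-scale Jacobians
  ## included by the callers' parameterization)
  logPostVar <- function(va, ve, r2) {
    d <- va * lam + ve
    ll <- -0.5 * sum(log(d)) - 0.5 * sum(r2 / d)
    lp_va <- -(prior$nu_g / 2 + 1) * log(va) -
      (prior$nu_g * prior$V_g / 2) / va
    lp_ve <- if (threshold) 0 else
      -(prior$nu_e / 2 + 1) * log(ve) - (prior$nu_e * prior$V_e / 2) / ve
    ll + lp_va + lp_ve
  }

  ## univariate slice sampler (stepping out + shrinkage, Neal 2003)
  slice1 <- function(logf, x0, w = 1.5, m = 30) {
    f0 <- logf(x0)
    z <- f0 + log(stats::runif(1))
    lo <- x0 - w * stats::runif(1)
    hi <- lo + w
    j <- floor(m * stats::runif(1)); k <- m - 1 - j
    while (j > 0 && logf(lo) > z) { lo <- lo - w; j <- j - 1 }
    while (k > 0 && logf(hi) > z) { hi <- hi + w; k <- k - 1 }
    repeat {
      x1 <- stats::runif(1, lo, hi)
      if (logf(x1) >= z) return(x1)
      if (x1 < x0) lo <- x1 else hi <- x1
    }
  }

  withSeed(mcmc$seed, {
    ys <- crossprod(U, y)          # rotated response (refreshed if latent)
    a <- numeric(n)
    va <- max(stats::var(y[is.finite(y)]) / 2, 0.1)
    ve <- if (threshold) 1 else va
    beta <- numeric(p)
    s <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      if (threshold) {
        ## genetic effects a | beta, va (conjugate, independent in the
        ## rotated basis; residual variance fixed at 1)
        resid_a <- drop(ys - Xs %*% beta)
        prec <- 1 + 1 / (va * lam[pos])
        mu_a <- resid_a[pos] / prec
        a[pos] <- mu_a + stats::rnorm(npos) / sqrt(prec)
        ## latent liability in the original basis, truncated by the label
        mu_l <- drop(X %*% beta) + drop(U %*% a)
        u <- stats::runif(n)
        pn <- stats::pnorm(-mu_l)
        q <- ifelse(label == 1, pn + u * (1 - pn), u * pn)
        q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
        l <- mu_l + stats::qnorm(q)
        ys <- crossprod(U, l)
      }
      ## beta | va, ve: exact GLS conditional under the marginal
      ## covariance diag(va lam + ve)
      d <- va * lam + ve
      Xw <- Xs / d
      XtVX <- crossprod(Xs, Xw)
      cX <- chol(XtVX)
      mean_b <- backsolve(cX, forwardsolve(t(cX), crossprod(Xw, ys)))
      beta <- drop(mean_b + backsolve(cX, stats::rnorm(p)))
      r2 <- drop(ys - Xs %*% beta)^2
      ## variances | beta by slice sampling on the marginal; the
      ## Gaussian model uses ridge-aligned coordinates
      ## (u, v) = (log va/ve, log(va + ve))
      if (threshold) {
        lva <- slice1(function(t) logPostVar(exp(t), 1, r2) + t, log(va))
        va <- exp(lva)
      } else {
        ## sweep 1: axis-aligned log-variance coordinates
        lva <- slice1(function(t) logPostVar(exp(t), ve, r2) + t, log(va))
        va <- exp(lva)
        lve <- slice1(function(t) logPostVar(va, exp(t), r2) + t, log(ve))
        ve <- exp(lve)
        ## sweep 2: ridge-aligned (log ratio, log total) coordinates
        u <- log(va / ve); v <- log(va + ve)
        uvPost <- function(u, v) {
          sig <- stats::plogis(u)
          va_ <- exp(v) * sig; ve_ <- exp(v) * (1 - sig)
          if (va_ <= 0 || ve_ <= 0) return(-Inf)
          ## Jacobian: dva dve = exp(2v) sig (1 - sig) du dv
          logPostVar(va_, ve_, r2) + 2 * v + log(sig) + log1p(-sig)
        }
        u <- slice1(function(x) uvPost(x, v), u, w = 2)
        v <- slice1(function(x) uvPost(u, x), v)
        sig <- stats::plogis(u)
        va <- exp(v) * sig; ve <- exp(v) * (1 - sig)
      }
      if (!is.finite(va) || !is.finite(ve) || any(!is.finite(beta)))
        stop("divergent chain at iteration ", it)
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
        s <- s + 1L
        beta_s[s, ] <- beta
        va_s[s] <- va
        ve_s[s] <- ve
      }
    }
  })
  list(beta = beta_s, va = va_s, ve = ve_s, n = n, p = p,
       retained = keep_n)
}

summarizeChains <- function(chains, ci = 0.95) {
  fx <- apply(chains$beta, 2, function(s) {
    h <- hpdInterval(s, ci)
    c(PM = mean(s), lower = h[["lower"]], upper = h[["upper"]],
      pMCMC = pmcmcStat(s), lag1 = lag1Autocorrelation(s),
      ess = effectiveSize(s))
  })
  fixed <- as.data.frame(t(fx))
  fixed <- cbind(term = rownames(fixed), fixed, row.names = NULL)
  vc <- rbind(
    genetic = c(PM = mean(chains$va), hpdInterval(chains$va, ci),
                lag1 = lag1Autocorrelation(chains$va),
                ess = effectiveSize(chains$va)),
    residual = c(PM = mean(chains$ve), hpdInterval(chains$ve, ci),
                 lag1 = lag1Autocorrelation(chains$ve),
                 ess = effectiveSize(chains$ve)))
  autocorr_ok <- all(stats::na.omit(c(fixed$lag1, vc[, "lag1"])) < 0.1)
  structure(list(fixed = fixed, varcomp = as.data.frame(vc),
                 retained = chains$retained,
                 autocorr_ok = autocorr_ok,
                 samples = chains),
            class = "stresshap_animal")
}

#' @export
print.stresshap_animal <- function(x, ...) {
  cat(sprintf("Animal-model posterior summary (%d retained samples%s)\n",
              x$retained,
              if (!x$autocorr_ok) "; WARNING lag-1 autocorrelation >= 0.1"
              else ""))
  print(x$fixed, digits = 3)
  cat("variance components:\n")
  print(x$varcomp, digits = 3)
  invisible(x)
}

#' Gaussian animal model via Gibbs sampling
#'
#' Fits \eqn{y = X\beta + g + e} with \eqn{g \sim N(0, v_a K)} and
#' \eqn{e \sim N(0, v_e I)}; flat prior on \eqn{\beta}, (V, nu)
#' inverse-gamma priors on the variances.  Fixed effects are reported
#' as posterior mean (PM), 95\% highest-posterior-density credible
#' interval and pMCMC = 2 min(P(\eqn{\theta}>0), P(\eqn{\theta}<0))
#' (floored at 2 / retained samples); lag-1 autocorrelation and
#' effective sample size are reported per parameter, with a flag when
#' autocorrelation exceeds the 0.1 diagnostic target.
#'
#' @param y named numeric trait vector (names = accession ids).
#' @param X fixed-effect design matrix (rownames = accession ids); an
#'   intercept column is added when absent.
#' @param K a \linkS4class{KinshipMatrix}.
#' @param prior a [priorSpec()].
#' @param mcmc an [mcmcSettings()].
#' @return object of class \code{"stresshap_animal"} with elements
#'   \code{fixed}, \code{varcomp}, \code{retained}, \code{autocorr_ok}
#'   and the raw \code{samples}.
#' @export
fitGaussianAnimalModel <- function(y, X = NULL, K, prior = priorSpec(),
                                   mcmc = mcmcSettings()) {
  stopifnot(is(K, "KinshipMatrix"))
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by accession id")
  keep <- !is.na(y)
  if (!is.null(X)) keep <- keep & !apply(is.na(as.matrix(X)[ids, , drop = FALSE]), 1, any)
  ids <- ids[keep]
  y <- y[ids]
  Km <- kinship(K)[ids, ids]
  Xm <- cbind(intercept = rep(1, length(ids)))
  if (!is.null(X)) {
    X <- as.matrix(X)
    Xm <- cbind(Xm, X[ids, , drop = FALSE])
  }
  chains <- animalGibbs(y, Xm, Km, prior, mcmc)
  summarizeChains(chains)
}

#' Threshold (probit) animal model for a binary trait
#'
#' Latent-liability augmentation: \eqn{l = X\beta + g + e},
#' \eqn{e \sim N(0, 1)} fixed for identifiability, observed class
#' = 1 iff \eqn{l > 0}.  Complete separation by a covariate yields a
#' prior-driven posterior and a warning, not an error.
#'
#' @param label named binary vector (1 = winter, 0 = summer).
#' @param X fixed-effect design matrix (rownames = accession ids).
#' @param K a \linkS4class{KinshipMatrix}.
#' @param prior a [priorSpec()]; default [thresholdPrior()].
#' @param mcmc an [mcmcSettings()].
#' @return \code{"stresshap_animal"} object; the residual variance row
#'   is the fixed value 1.
#' @export
fitThresholdAnimalModel <- function(label, X, K, prior = thresholdPrior(),
                                    mcmc = mcmcSettings()) {
  stopifnot(is(K, "KinshipMatrix"))
  ids <- names(label)
  if (is.null(ids)) stop("label must be named by accession id")
  if (length(unique(label[!is.na(label)])) < 2)
    stop("both classes must be present")
  keep <- !is.na(label) & !apply(is.na(as.matrix(X)[ids, , drop = FALSE]), 1, any)
  ids <- ids[keep]
  label <- label[ids]
  Xm <- cbind(intercept = 1, as.matrix(X)[ids, , drop = FALSE])
  ## complete-separation check per covariate
  for (j in seq(2, ncol(Xm))) {
    x1 <- Xm[label == 1, j]; x0 <- Xm[label == 0, j]
    if (max(x0) < min(x1) || max(x1) < min(x0))
      warning("complete separation by covariate '", colnames(Xm)[j],
              "'; posterior is prior-driven")
  }
  Km <- kinship(K)[ids, ids]
  chains <- animalGibbs(rep(0, length(ids)), Xm, Km, prior, mcmc,
                        threshold = TRUE, label = label)
  summarizeChains(chains)
}

singleStresses <- c("Drought", "P_rapae", "P_xylostella",
                    "F_occidentalis", "M_persicae")

#' Trade-off models across single stresses
#'
#' For each single stress, fits the Gaussian animal model with the
#' other single-stress responses plus life cycle (winter = 1) as fixed
#' effects, on complete cases across the five responses.
#'
#' @param responses stress-response data.frame (accession_id + columns).
#' @param life_cycle data.frame from [classifyLifeCycle()] (or a named
#'   \code{strategy} vector).
#' @param K a \linkS4class{KinshipMatrix}.
#' @param prior,mcmc passed to [fitGaussianAnimalModel()].
#' @return named list of \code{"stresshap_animal"} objects, one per
#'   single stress, plus a combined \code{table} attribute
#'   (term-per-row summary across models).
#' @export
tradeOffModels <- function(responses, life_cycle, K, prior = priorSpec(),
                           mcmc = mcmcSettings()) {
  lc <- lifeCycleVector(life_cycle)
  cc <- stats::complete.cases(responses[singleStresses])
  resp <- responses[cc, ]
  fits <- list()
  for (tr in singleStresses) {
    others <- setdiff(singleStresses, tr)
    X <- as.matrix(resp[others])
    X <- cbind(X, life_cycle_winter = as.numeric(lc[resp$accession_id] == "winter"))
    rownames(X) <- resp$accession_id
    y <- stats::setNames(resp[[tr]], resp$accession_id)
    fits[[tr]] <- fitGaussianAnimalModel(y, X, K, prior, mcmc)
  }
  tab <- do.call(rbind, lapply(names(fits), function(tr)
    cbind(response = tr, fits[[tr]]$fixed)))
  attr(fits, "table") <- tab
  fits
}

#' Life-cycle / gradient animal models per stress (model type 1)
#'
#' One Gaussian animal model per stress response with life cycle
#' (winter = 1), elevation (m), latitude and longitude (degrees,
#' untransformed) as fixed effects.
#'
#' @inheritParams tradeOffModels
#' @param geo geographic table (accession_id, latitude, longitude,
#'   elevation).
#' @return named list of \code{"stresshap_animal"} objects with a
#'   combined \code{table} attribute.
#' @export
stressGradientModels <- function(responses, life_cycle, geo, K,
                                 prior = priorSpec(),
                                 mcmc = mcmcSettings()) {
  lc <- lifeCycleVector(life_cycle)
  traits <- setdiff(names(responses), "accession_id")
  gi <- match(responses$accession_id, geo$accession_id)
  X <- cbind(life_cycle_winter = as.numeric(lc[responses$accession_id] == "winter"),
             elevation = geo$elevation[gi],
             latitude = geo$latitude[gi],
             longitude = geo$longitude[gi])
  rownames(X) <- responses$accession_id
  fits <- list()
  for (tr in traits) {
    y <- stats::setNames(responses[[tr]], responses$accession_id)
    fits[[tr]] <- fitGaussianAnimalModel(y, X, K, prior, mcmc)
  }
  tab <- do.call(rbind, lapply(names(fits), function(tr)
    cbind(response = tr, fits[[tr]]$fixed)))
  attr(fits, "table") <- tab
  fits
}

lifeCycleVector <- function(life_cycle) {
  if (is.data.frame(life_cycle))
    stats::setNames(life_cycle$strategy, life_cycle$accession_id)
  else life_cycle
}
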