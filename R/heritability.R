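## Marker-based narrow-sense heritability by REML.
##
## Model: y = mu + g + e, g ~ N(0, va K), e ~ N(0, ve I).  One
## eigendecomposition of K reduces the REML problem to a 1-D search over
## the variance ratio delta = va / ve: in the rotated basis the
## covariance is diagonal, ve (delta lambda_i + 1).

#' Estimate narrow-sense heritability for one trait
#'
#' @param y named numeric vector of per-accession trait values (names =
#'   accession ids); NAs dropped.
#' @param K a \linkS4class{KinshipMatrix} covering all accessions in
#'   \code{y}.
#' @param covariates optional numeric matrix of fixed covariates
#'   (rownames = accession ids); an intercept is always included.
#' @return list of class \code{"stresshap_h2"}: \code{h2}, \code{va},
#'   \code{ve}, \code{se_h2}, \code{n_accessions}, \code{loglik},
#'   \code{boundary} (TRUE when the optimum sits on the search bound),
#'   \code{degenerate} (TRUE for the flat identity-kinship case).
#' @details The profiled restricted log-likelihood is maximized over
#'   \code{log(delta)} in [-10, 10] by Brent search.  With an identity
#'   (equal-eigenvalue) kinship the likelihood is flat in the ratio; the
#'   estimator then returns h2 = 0 with a warning instead of an
#'   arbitrary interior value.  The standard error comes from the
#'   numerical curvature of the profile likelihood in h2.
#' @examples
#' truth <- simulationTruth(n_accessions = 80, n_markers = 300, seed = 3)
#' sim <- simulateGenotypesIbd(truth)
#' K <- computeKinship(sim$geno)
#' y <- drop(chol(kinship(K) + diag(1e-6, 80)) %*% rnorm(80))
#' names(y) <- accessionIds(K)
#' estimateH2(y, K)$h2  # near 1: noiseless additive trait
#' @export
estimateH2 <- function(y, K, covariates = NULL) {
  stopifnot(is(K, "KinshipMatrix"))
  y <- y[!is.na(y)]
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by accession id")
  if (!all(ids %in% accessionIds(K)))
    stop("trait values present for accessions missing from K")
  n <- length(y)
  if (n < 3) stop("need >= 3 accessions")
  if (n < 30) warning("fewer than 30 accessions; h2 estimate will be noisy")
  if (stats::var(y) == 0) stop("zero trait variance")
  Km <- kinship(K)[ids, ids]
  eg <- eigen(Km, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("K is not positive semi-definite; apply the ridge repair first")
  lam <- pmax(eg$values, 0)
  X <- cbind(intercept = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates)[ids, , drop = FALSE])
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)
  p <- ncol(X)

  remlNegLoglik <- function(logdelta) {
    v <- exp(logdelta) * lam + 1
    XtVX <- crossprod(Xs / v, Xs)
    beta <- solve(XtVX, crossprod(Xs / v, ys))
    r <- ys - Xs %*% beta
    quad <- sum(r^2 / v)
    ve <- quad / (n - p)
    0.5 * ((n - p) * log(2 * pi * ve) + (n - p) +
           sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus)
  }

  if (stats::sd(lam) < 1e-10) {
    warning("equal-eigenvalue (identity-like) kinship: heritability is ",
            "not identified; returning h2 = 0")
    ve <- stats::var(y)
    return(structure(list(h2 = 0, va = 0, ve = ve, se_h2 = NA_real_,
                          n_accessions = n, loglik = NA_real_,
                          boundary = TRUE, degenerate = TRUE),
                     class = "stresshap_h2"))
  }

  opt <- stats::optimize(remlNegLoglik, interval = c(-10, 10) * log(10),
                         tol = 1e-9)
  logdelta <- opt$minimum
  boundary <- min(abs(logdelta - c(-10, 10) * log(10))) < 1e-3
  delta <- exp(logdelta)
  v <- delta * lam + 1
  XtVX <- crossprod(Xs / v, Xs)
  beta <- solve(XtVX, crossprod(Xs / v, ys))
  r <- ys - Xs %*% beta
  ve <- sum(r^2 / v) / (n - p)
  va <- delta * ve
  h2 <- va / (va + ve)
  if (boundary) {                         # report the limit point exactly
    h2 <- round(h2)
    if (h2 == 0) va <- 0 else ve <- 0
  }

  ## curvature of the profile REML in h2 (delta method through
  ## logdelta = log(h2 / (1 - h2)))
  se_h2 <- NA_real_
  if (!boundary) {
    eps <- 1e-3
    f0 <- remlNegLoglik(logdelta)
    fp <- remlNegLoglik(logdelta + eps)
    fm <- remlNegLoglik(logdelta - eps)
    hess <- (fp + fm - 2 * f0) / eps^2
    if (is.finite(hess) && hess > 0) {
      se_logdelta <- sqrt(1 / hess)
      se_h2 <- se_logdelta * h2 * (1 - h2)  # d h2 / d logdelta
    }
  }
  structure(list(h2 = h2, va = va, ve = ve, se_h2 = se_h2,
                 n_accessions = n, loglik = -opt$objective,
                 boundary = boundary, degenerate = FALSE),
            class = "stresshap_h2")
}

#' Heritability table across stress responses
#'
#' One row per stress column with the summary-table layout used for
#' accession panels: Min, Mean, Max, CV% (100 sd / mean on the trait's
#' own scale), N, h2, va, ve.  Per-trait failures (e.g. a constant
#' column) are flagged in the \code{note} column and do not abort the
#' other traits.
#'
#' @param responses data.frame with \code{accession_id} plus one column
#'   per stress response.
#' @param K a \linkS4class{KinshipMatrix}.
#' @return data.frame, one row per trait.
#' @export
h2Table <- function(responses, K) {
  traits <- setdiff(names(responses), "accession_id")
  rows <- lapply(traits, function(tr) {
    y <- stats::setNames(responses[[tr]], responses$accession_id)
    yv <- y[!is.na(y)]
    base <- data.frame(trait = tr, min = min(yv), mean = mean(yv),
                       max = max(yv), cv = 100 * stats::sd(yv) / mean(yv),
                       n = length(yv))
    est <- tryCatch(estimateH2(y, K), error = function(e) e)
    if (inherits(est, "error")) {
      cbind(base, h2 = NA_real_, va = NA_real_, ve = NA_real_,
            se_h2 = NA_real_, note = conditionMessage(est))
    } else {
      cbind(base, h2 = est$h2, va = est$va, ve = est$ve,
            se_h2 = est$se_h2,
            note = if (est$boundary) "boundary" else "")
    }
  })
  do.call(rbind, rows)
}
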