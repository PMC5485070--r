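## Two-trait multi-trait mixed model (MTMM) GWAS.
##
## Stacked model for traits p1, p2 over n accessions (trait-block outer
## ordering, y = [p1; p2]):
##   y = s1 mu1 + s2 mu2 + x beta + (x o s1) alpha + upsilon,
##   upsilon ~ N(0, Vg (x) K + Ve (x) I_n),
## with Vg the 2x2 genetic (kinship-structured) trait covariance and Ve
## the residual trait covariance.  Variance components are estimated
## once under the null by REML and held fixed across SNPs (plug-in GLS);
## each SNP is tested with three F tests: full (beta, alpha | 2 df),
## common (beta | 1 df) and specific (alpha given beta | 1 df).

summerResistantTraits <- c("P_rapae", "P_xylostella", "Drought_Pieris",
                           "Botrytis_Pieris")
winterResistantTraits <- c("F_occidentalis", "M_persicae", "Drought")

#' Composite trait vectors for the MTMM scan
#'
#' p1 = PC1 of the responses where summer annuals are the more
#' resistant class (P. rapae, P. xylostella, Drought&Pieris,
#' Botrytis&Pieris); p2 = PC1 of the winter-resistant responses
#' (F. occidentalis, M. persicae, Drought).  Columns are standardized
#' before PCA; each composite is oriented so that it correlates
#' positively with the group's mean standardized response, then scaled
#' to unit variance.
#'
#' @param responses data.frame with \code{accession_id} and all seven
#'   response columns; complete cases are used.
#' @return list with \code{p1}, \code{p2} (named unit-variance
#'   vectors), \code{explained_fraction_p1},
#'   \code{explained_fraction_p2}, \code{n}.
#' @export
buildTraitVectors <- function(responses) {
  need <- c(summerResistantTraits, winterResistantTraits)
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("responses lack columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(responses[need])
  if (sum(cc) < 3) stop("fewer than 3 complete accessions")
  resp <- responses[cc, ]
  ids <- resp$accession_id
  groupPc1 <- function(cols) {
    Z <- scale(as.matrix(resp[cols]))
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    sc <- pc$x[, 1]
    if (stats::cor(sc, rowMeans(Z)) < 0) sc <- -sc       # fixed sign convention
    list(score = stats::setNames(drop(scale(sc)), ids),
         explained = pc$sdev[1]^2 / sum(pc$sdev^2))
  }
  g1 <- groupPc1(summerResistantTraits)
  g2 <- groupPc1(winterResistantTraits)
  list(p1 = g1$score, p2 = g2$score,
       explained_fraction_p1 = g1$explained,
       explained_fraction_p2 = g2$explained,
       n = length(ids))
}

## negative restricted log-likelihood for the 2-trait model, profiled
## over the two trait intercepts; th = log-Cholesky parameters
## (t1..t3 -> Lg, t4..t6 -> Le)
mtmmNegLoglik <- function(th, lam, Y, u) {
  Lg <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2)
  Le <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2)
  Vg <- tcrossprod(Lg); Ve <- tcrossprod(Le)
  c11 <- lam * Vg[1, 1] + Ve[1, 1]
  c22 <- lam * Vg[2, 2] + Ve[2, 2]
  c12 <- lam * Vg[1, 2] + Ve[1, 2]
  det_i <- c11 * c22 - c12^2
  if (any(det_i <= 0)) return(1e10)
  i11 <- c22 / det_i; i22 <- c11 / det_i; i12 <- -c12 / det_i
  ## A = X' Sigma^-1 X (2x2), b = X' Sigma^-1 y
  u2 <- u^2
  A <- matrix(c(sum(u2 * i11), sum(u2 * i12),
                sum(u2 * i12), sum(u2 * i22)), 2)
  b <- c(sum(u * (i11 * Y[, 1] + i12 * Y[, 2])),
         sum(u * (i12 * Y[, 1] + i22 * Y[, 2])))
  detA <- A[1, 1] * A[2, 2] - A[1, 2]^2
  if (detA <= 1e-12 * abs(A[1, 1] * A[2, 2])) return(1e10)
  beta <- solve(A, b)
  r1 <- Y[, 1] - u * beta[1]
  r2 <- Y[, 2] - u * beta[2]
  quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  0.5 * (sum(log(det_i)) + log(detA) + quad)
}

#' REML variance components for the two-trait MTMM null model
#'
#' Estimates the 2x2 genetic and residual trait covariance matrices
#' (6 free parameters, PSD enforced by log-Cholesky parameterization)
#' for the stacked 2n model with covariance Vg (x) K + Ve (x) I, by
#' REML with trait intercepts as fixed effects.  Initialized from
#' single-trait REML fits.
#'
#' @param p1,p2 named trait vectors (same accessions).
#' @param K a \linkS4class{KinshipMatrix}.
#' @return list of class \code{"stresshap_mtmm"}: \code{Vg}, \code{Ve},
#'   \code{reml_loglik}, \code{convergence}, \code{identifiable}
#'   (FALSE for an equal-eigenvalue kinship where only Vg + Ve is
#'   identified).
#' @export
fitMtmmVarcomp <- function(p1, p2, K) {
  stopifnot(is(K, "KinshipMatrix"))
  ids <- names(p1)
  if (is.null(ids) || !identical(ids, names(p2)))
    stop("p1 and p2 must be named and aligned")
  n <- length(p1)
  if (n < 20) warning("fewer than 20 accessions; MTMM components unstable")
  eg <- eigen(kinship(K)[ids, ids], symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  identifiable <- stats::sd(lam) > 1e-10
  if (!identifiable)
    warning("equal-eigenvalue (identity-like) kinship: only Vg + Ve is ",
            "identified")
  U <- eg$vectors
  Y <- cbind(crossprod(U, p1), crossprod(U, p2))
  u <- drop(crossprod(U, rep(1, n)))
  ## single-trait initialization
  init1 <- tryCatch(suppressWarnings(estimateH2(p1, K)),
                    error = function(e) NULL)
  init2 <- tryCatch(suppressWarnings(estimateH2(p2, K)),
                    error = function(e) NULL)
  vg1 <- if (!is.null(init1)) max(init1$va, 1e-4) else stats::var(p1) / 2
  vg2 <- if (!is.null(init2)) max(init2$va, 1e-4) else stats::var(p2) / 2
  ve1 <- if (!is.null(init1)) max(init1$ve, 1e-4) else stats::var(p1) / 2
  ve2 <- if (!is.null(init2)) max(init2$ve, 1e-4) else stats::var(p2) / 2
  th0 <- c(log(sqrt(vg1)), 0, log(sqrt(vg2)), log(sqrt(ve1)), 0,
           log(sqrt(ve2)))
  ## Nelder-Mead with restarts: a boundary optimum (e.g. perfectly
  ## correlated traits) can exhaust maxit while no longer improving
  opt <- stats::optim(th0, mtmmNegLoglik, lam = lam, Y = Y, u = u,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  for (r in 1:3) {
    if (opt$convergence == 0) break
    opt2 <- stats::optim(opt$par, mtmmNegLoglik, lam = lam, Y = Y, u = u,
                         method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-12))
    stalled <- (opt$value - opt2$value) < 1e-8
    opt <- opt2
    if (stalled) break
  }
  if (opt$convergence != 0)
    warning("MTMM REML stopped before full convergence (optim code ",
            opt$convergence, "); returning the best iterate. ",
            "A diverging correlation (duplicated traits) is the usual cause.")
  th <- opt$par
  Lg <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2)
  Le <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2)
  Vg <- tcrossprod(Lg); Ve <- tcrossprod(Le)
  dimnames(Vg) <- dimnames(Ve) <- list(c("p1", "p2"), c("p1", "p2"))
  structure(list(Vg = Vg, Ve = Ve, reml_loglik = -opt$value,
                 convergence = opt$convergence == 0,
                 identifiable = identifiable, ids = ids,
                 K = kinship(K)[ids, ids]),
            class = "stresshap_mtmm")
}

#' Per-SNP GLS F tests (full / common / specific)
#'
#' For every marker passing the MAF filter, fits the stacked two-trait
#' model by GLS under the plug-in covariance
#' \eqn{\Omega = Vg \otimes K + Ve \otimes I} (held fixed across SNPs)
#' and reports three F tests: \emph{full} (beta = alpha = 0 against the
#' intercept-only null; 2 numerator df), \emph{common} (beta alone; 1
#' df) and \emph{specific} (alpha given beta; 1 df), with exact
#' finite-sample denominator df 2n - rank(design).
#'
#' @param geno a \linkS4class{GenotypeMatrix} covering the trait
#'   accessions.
#' @param fit a \code{"stresshap_mtmm"} object (or any list with 2x2
#'   \code{Vg} and \code{Ve}, e.g. an identity plug-in for checks).
#' @param p1,p2 named composite trait vectors.
#' @param maf_min markers kept when MAF is strictly greater than this
#'   (default 0.05).
#' @return data.frame: \code{marker}, \code{chromosome},
#'   \code{position}, \code{maf}, \code{beta}, \code{alpha},
#'   \code{p_full}, \code{p_common}, \code{p_specific}.  SNPs constant
#'   across the analysed accessions are skipped with a message.
#' @export
glsFTests <- function(geno, fit, p1, p2, maf_min = 0.05) {
  stopifnot(is(geno, "GenotypeMatrix"))
  ids <- names(p1)
  if (!identical(ids, names(p2))) stop("p1/p2 accession mismatch")
  if (!all(ids %in% accessionIds(geno)))
    stop("trait accessions missing from genotypes")
  geno <- geno[match(ids, accessionIds(geno)), ]
  geno <- mafFilter(geno, maf_min)
  m <- nMarkers(geno)
  if (m == 0) stop("no markers pass the MAF filter")
  n <- length(ids)
  X <- callMatrix(geno)
  K <- NULL
  Vg <- fit$Vg; Ve <- fit$Ve
  ## Omega = Vg (x) K + Ve (x) I; whitened per kinship eigenvector
  if (!is.null(fit$ids)) {
    if (!all(ids %in% fit$ids)) stop("fit does not cover the trait accessions")
  }
  Kfull <- fit$K
  if (is(fit$K, "KinshipMatrix")) Kfull <- kinship(fit$K)
  if (is.null(Kfull)) {
    ## reconstruct from the eigen-space implied by an identity kinship
    Kfull <- diag(n)
    dimnames(Kfull) <- list(ids, ids)
  }
  eg <- eigen(Kfull[ids, ids], symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  y1 <- drop(crossprod(U, p1)); y2 <- drop(crossprod(U, p2))
  u <- drop(crossprod(U, rep(1, n)))
  Xs <- crossprod(U, X)
  ## per-index 2x2 covariance C_i = lam_i Vg + Ve -> inverse Cholesky
  c11 <- lam * Vg[1, 1] + Ve[1, 1]
  c22 <- lam * Vg[2, 2] + Ve[2, 2]
  c12 <- lam * Vg[1, 2] + Ve[1, 2]
  det_i <- c11 * c22 - c12^2
  if (any(det_i <= 0)) stop("plug-in covariance not invertible")
  ## whitening W_i: lower Cholesky of C_i^-1; rows of each 2-block are
  ## (trait1_i, trait2_i); W_i = inv(L_i) with C_i = L_i L_i'
  l11 <- sqrt(c11)
  l21 <- c12 / l11
  l22 <- sqrt(c22 - l21^2)
  ## solve L_i z = v for each 2-vector v: z1 = v1/l11; z2 = (v2 - l21 z1)/l22
  whiten <- function(v1, v2) {
    z1 <- v1 / l11
    z2 <- (v2 - l21 * z1) / l22
    cbind(z1, z2)
  }
  yw <- whiten(y1, y2)                     # 2n whitened response
  s1w <- whiten(u, rep(0, n))              # trait-1 intercept
  s2w <- whiten(rep(0, n), u)              # trait-2 intercept
  yv <- as.vector(yw)
  N0 <- cbind(as.vector(s1w), as.vector(s2w))
  q0 <- qr(N0)
  rss_null <- sum(qr.resid(q0, yv)^2)
  maf <- minorAlleleFrequency(geno)
  mk <- markerInfo(geno)
  out <- data.frame(marker = names(mk),
                    chromosome = as.character(GenomicRanges::seqnames(mk)),
                    position = GenomicRanges::start(mk),
                    maf = maf, beta = NA_real_, alpha = NA_real_,
                    F_full = NA_real_, F_common = NA_real_,
                    F_specific = NA_real_,
                    p_full = NA_real_, p_common = NA_real_,
                    p_specific = NA_real_, row.names = NULL)
  skipped <- 0L
  for (j in seq_len(m)) {
    xs <- Xs[, j]
    if (stats::var(X[, j]) == 0) { skipped <- skipped + 1L; next }
    xcw <- whiten(xs, xs)                  # common-effect regressor
    xsw <- whiten(xs, rep(0, n))           # trait-1-specific regressor
    Dc <- cbind(N0, as.vector(xcw))
    Df <- cbind(Dc, as.vector(xsw))
    qc <- qr(Dc); qf <- qr(Df)
    rss_c <- sum(qr.resid(qc, yv)^2)
    rss_f <- sum(qr.resid(qf, yv)^2)
    df_f <- 2 * n - qf$rank
    df_c <- 2 * n - qc$rank
    F_full <- ((rss_null - rss_f) / 2) / (rss_f / df_f)
    F_common <- ((rss_null - rss_c) / 1) / (rss_c / df_c)
    F_spec <- ((rss_c - rss_f) / 1) / (rss_f / df_f)
    cf <- qr.coef(qf, yv)
    out$beta[j] <- cf[3]
    out$alpha[j] <- cf[4]
    out$F_full[j] <- F_full
    out$F_common[j] <- F_common
    out$F_specific[j] <- F_spec
    out$p_full[j] <- stats::pf(F_full, 2, df_f, lower.tail = FALSE)
    out$p_common[j] <- stats::pf(F_common, 1, df_c, lower.tail = FALSE)
    out$p_specific[j] <- stats::pf(F_spec, 1, df_f, lower.tail = FALSE)
  }
  if (skipped) message(skipped, " constant SNP(s) skipped")
  out[!is.na(out$p_full), , drop = FALSE]
}

#' Merge significant SNPs into QTL regions
#'
#' SNPs with \eqn{-\log_{10}(p) \ge} \code{neg_log10_threshold} for the
#' chosen test seed a window of \code{window_bp} total width centred on
#' the SNP (floored at position 1); overlapping or adjacent windows on
#' one chromosome merge into a single region.
#'
#' @param results data.frame from [glsFTests()].
#' @param test \code{"specific"}, \code{"full"} or \code{"common"}.
#' @param neg_log10_threshold significance threshold on -log10(p),
#'   default 4.
#' @param window_bp total window width in bp (default 20000, i.e. +-10
#'   kb).
#' @return \link[GenomicRanges]{GRanges} of merged regions (1-based,
#'   inclusive) with metadata columns \code{region}, \code{n_snps},
#'   \code{peak_neg_log10}, \code{snps} (comma-separated member ids).
#' @export
selectQtlRegions <- function(results, test = c("specific", "full", "common"),
                             neg_log10_threshold = 4, window_bp = 20000) {
  test <- match.arg(test)
  p <- results[[paste0("p_", test)]]
  sig <- which(-log10(p) >= neg_log10_threshold)
  if (!length(sig))
    return(GenomicRanges::GRanges())
  half <- window_bp / 2
  seeds <- GenomicRanges::GRanges(
    results$chromosome[sig],
    IRanges::IRanges(pmax(1, floor(results$position[sig] - half)),
                     floor(results$position[sig] + half)))
  regions <- GenomicRanges::reduce(GenomicRanges::sort(seeds))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(results$chromosome[sig],
                           IRanges::IRanges(results$position[sig], width = 1)),
    regions)
  nl <- -log10(p[sig])
  S4Vectors::mcols(regions)$region <- seq_along(regions)
  S4Vectors::mcols(regions)$n_snps <-
    as.integer(table(factor(S4Vectors::subjectHits(hits),
                            levels = seq_along(regions))))
  S4Vectors::mcols(regions)$peak_neg_log10 <- vapply(
    seq_along(regions), function(r)
      max(nl[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == r]]),
    numeric(1))
  S4Vectors::mcols(regions)$snps <- vapply(
    seq_along(regions), function(r)
      paste(results$marker[sig][S4Vectors::queryHits(hits)[
        S4Vectors::subjectHits(hits) == r]], collapse = ","),
    character(1))
  regions
}

#' Pairwise LD (r squared) around a focal marker
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param focal marker id.
#' @param window_bp half-window in bp around the focal position.
#' @return data.frame \code{marker}, \code{position}, \code{r2}
#'   (squared Pearson correlation of the 0/1 columns; NA for
#'   monomorphic companions).
#' @export
ldR2 <- function(geno, focal, window_bp = 20000) {
  mk <- markerInfo(geno)
  fi <- match(focal, names(mk))
  if (is.na(fi)) stop("focal marker not found: ", focal)
  chr <- as.character(GenomicRanges::seqnames(mk))
  pos <- GenomicRanges::start(mk)
  sel <- which(chr == chr[fi] & abs(pos - pos[fi]) <= window_bp)
  X <- callMatrix(geno)
  xf <- X[, fi]
  r2 <- vapply(sel, function(j) {
    xj <- X[, j]
    if (stats::var(xj) == 0 || stats::var(xf) == 0) return(NA_real_)
    stats::cor(xf, xj)^2
  }, numeric(1))
  data.frame(marker = names(mk)[sel], position = pos[sel], r2 = r2,
             row.names = NULL)
}
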