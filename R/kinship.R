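## Geographic subsetting, allele frequencies and marker-based kinship.

#' Subset a panel to a geographic window
#'
#' Keeps exactly the accessions whose collection site satisfies
#' latitude >= \code{lat_min}, \code{lon_min} <= longitude <=
#' \code{lon_max} and elevation <= \code{elev_max}; all bounds are
#' inclusive.  The defaults are the European window used for
#' Hapmap-panel work (lat >= 30, lon in [-50, 50], elevation <= 2000 m).
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param geo data.frame with columns \code{accession_id},
#'   \code{latitude}, \code{longitude}, \code{elevation}.
#' @param lat_min,lon_min,lon_max,elev_max window bounds (degrees /
#'   metres), all inclusive.
#' @param strict if \code{TRUE}, an accession without a geographic
#'   record is an error; by default such accessions are excluded with a
#'   warning.
#' @return The subsetted \linkS4class{GenotypeMatrix}.
#' @export
geographicSubset <- function(geno, geo, lat_min = 30, lon_min = -50,
                             lon_max = 50, elev_max = 2000,
                             strict = FALSE) {
  stopifnot(is(geno, "GenotypeMatrix"))
  geo <- validateGeoTable(geo)
  ids <- accessionIds(geno)
  idx <- match(ids, geo$accession_id)
  nogeo <- is.na(idx)
  if (any(nogeo)) {
    if (strict)
      stop("accessions without geographic record: ",
           paste(utils::head(ids[nogeo], 5), collapse = ", "))
    warning(sum(nogeo), " accession(s) without geographic record excluded")
  }
  keep <- !nogeo
  g <- geo[idx[keep], ]
  ok <- g$latitude >= lat_min & g$longitude >= lon_min &
    g$longitude <= lon_max & g$elevation <= elev_max
  geno[which(keep)[ok], ]
}

#' Minor allele frequency per marker
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @return named numeric vector, \code{min(p, 1 - p)} with \code{p} the
#'   column mean of the 0/1 calls; values in [0, 0.5].
#' @export
minorAlleleFrequency <- function(geno) {
  stopifnot(is(geno, "GenotypeMatrix"))
  p <- colMeans(callMatrix(geno))
  pmin(p, 1 - p)
}

#' Filter markers by minor allele frequency
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param maf_min retain markers with MAF strictly greater than this.
#' @return The filtered \linkS4class{GenotypeMatrix}.
#' @export
mafFilter <- function(geno, maf_min = 0.05) {
  geno[, minorAlleleFrequency(geno) > maf_min]
}

#' Marker-based kinship matrix
#'
#' @param geno a \linkS4class{GenotypeMatrix} (>= 2 polymorphic markers).
#' @param estimator \code{"standardized"}: \eqn{K = Z Z^T / m} with Z the
#'   column-centred, column-scaled (unit variance) call matrix over the
#'   polymorphic markers (VanRaden-type cross-product); \code{"ibs"}:
#'   \eqn{K_{ij}} = proportion of markers with identical calls.
#' @details The estimator choice propagates into heritability and MTMM
#'   results, so it is recorded in the returned object.  If the smallest
#'   eigenvalue of the raw estimate is below -1e-8, a ridge
#'   \eqn{\delta I}, \eqn{\delta = |\lambda_{min}| + 10^{-8}}, is added
#'   and recorded so that downstream solvers receive a PSD matrix.
#' @return A \linkS4class{KinshipMatrix}.
#' @export
computeKinship <- function(geno, estimator = c("standardized", "ibs")) {
  stopifnot(is(geno, "GenotypeMatrix"))
  estimator <- match.arg(estimator)
  X <- callMatrix(geno)
  maf <- minorAlleleFrequency(geno)
  if (estimator == "standardized") {
    poly <- maf > 0
    if (sum(poly) < 2) stop("need >= 2 polymorphic markers for kinship")
    Z <- scale(X[, poly, drop = FALSE])
    K <- tcrossprod(Z) / ncol(Z)
  } else {
    if (!any(maf > 0)) stop("all markers monomorphic")
    m <- ncol(X)
    ## proportion of identical 0/1 calls
    xy <- tcrossprod(X)
    ones <- tcrossprod(1 - X)
    K <- (xy + ones) / m
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(accessionIds(geno), accessionIds(geno))
  lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ridge <- 0
  if (lam_min < -1e-8) {
    ridge <- abs(lam_min) + 1e-8
    K <- K + diag(ridge, nrow(K))
  }
  new("KinshipMatrix", K = K, estimator = estimator, ridge = ridge)
}

#' Write / read a kinship matrix as TSV
#'
#' @param k a \linkS4class{KinshipMatrix}; \code{path} a TSV path.
#' @return \code{readKinship} returns a \linkS4class{KinshipMatrix}
#'   (estimator recorded in a header comment line).
#' @rdname kinshipIO
#' @param path TSV path.
#' @export
writeKinship <- function(k, path) {
  stopifnot(is(k, "KinshipMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# estimator=%s ridge=%.17g", k@estimator, k@ridge), con)
  utils::write.table(data.frame(accession_id = rownames(k@K), k@K,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname kinshipIO
#' @export
readKinship <- function(path) {
  header <- readLines(path, n = 1)
  est <- "standardized"; ridge <- 0
  if (startsWith(header, "#")) {
    est <- sub(".*estimator=(\\S+).*", "\\1", header)
    ridge <- as.numeric(sub(".*ridge=(\\S+).*", "\\1", header))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  K <- as.matrix(tab[, -1, drop = FALSE])
  rownames(K) <- tab[[1]]
  K <- (K + t(K)) / 2
  new("KinshipMatrix", K = K, estimator = est, ridge = ridge)
}
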