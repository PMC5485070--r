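#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

#' Genotype matrix for a panel of inbred accessions
#'
#' Holds biallelic SNP calls for inbred lines in haploid 0/1 coding
#' (allele dosage of the counted allele), together with the genomic
#' coordinates of every marker.  Rows are accessions, columns are
#' markers; markers are kept sorted by (chromosome, position).
#'
#' Heterozygous or missing calls are rejected by the validity method:
#' the intended input is a post-QC, imputed marker set for inbred
#' lines, where every call is exactly 0 or 1.
#'
#' @slot calls numeric matrix (accessions x markers) with entries in
#'   \{0, 1\}; rownames are accession ids, colnames marker ids.
#' @slot markers \link[GenomicRanges]{GRanges} of width-1 marker
#'   positions (1-based), one per column of \code{calls}, in column
#'   order.
#'
#' @seealso [readGenotypes()], [computeKinship()], [pcaMarkers()]
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", markers = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  calls <- object@calls
  if (is.null(rownames(calls)) || anyDuplicated(rownames(calls)))
    msg <- c(msg, "accession ids (rownames) must be present and unique")
  if (anyNA(calls) || !all(calls == 0 | calls == 1))
    msg <- c(msg, "genotype calls must be exactly 0 or 1 (no NA, no heterozygotes)")
  if (ncol(calls) != length(object@markers))
    msg <- c(msg, "number of markers must match number of call columns")
  if (length(object@markers) > 1) {
    chr <- as.character(GenomicRanges::seqnames(object@markers))
    pos <- GenomicRanges::start(object@markers)
    for (cc in unique(chr)) {
      p <- pos[chr == cc]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, sprintf(
          "marker positions must be strictly increasing within chromosome %s", cc))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls accessions x markers matrix of 0/1 calls with rownames
#'   (accession ids); colnames are taken as marker ids (generated when
#'   absent).
#' @param chromosome character/factor vector of marker chromosomes.
#' @param position integer vector of 1-based marker positions (bp).
#' @param sort logical; sort markers by (chromosome, position) first.
#' @return A validated \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 1, 0), 2, 2,
#'                            dimnames = list(c("a1", "a2"), NULL)),
#'                     chromosome = c("1", "1"), position = c(100L, 200L))
#' nMarkers(g)
#' @export
GenotypeMatrix <- function(calls, chromosome, position, sort = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("m", seq_len(ncol(calls)))
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  if (length(chromosome) != ncol(calls) || length(position) != ncol(calls))
    stop("chromosome/position must have one entry per marker column")
  if (sort) {
    o <- order(chromosome, position)
    calls <- calls[, o, drop = FALSE]
    chromosome <- chromosome[o]
    position <- position[o]
  }
  gr <- GenomicRanges::GRanges(chromosome,
                               IRanges::IRanges(position, width = 1L))
  names(gr) <- colnames(calls)
  new("GenotypeMatrix", calls = calls, markers = gr)
}

#' Marker-based kinship matrix
#'
#' Symmetric n x n relatedness matrix used as the covariance of the
#' additive genetic random effect in heritability estimation, animal
#' models and the MTMM scan.  When the raw estimate has a negative
#' eigenvalue below -1e-8 it is ridge-repaired by adding
#' \eqn{\delta I} with \eqn{\delta = |\lambda_{min}| + 10^{-8}}; the
#' applied \code{ridge} is recorded.
#'
#' @slot K symmetric numeric matrix, dimnames = accession ids.
#' @slot estimator character, \code{"standardized"} or \code{"ibs"}.
#' @slot ridge numeric, the ridge added to the diagonal (0 if none).
#' @export
setClass("KinshipMatrix",
  representation(K = "matrix", estimator = "character", ridge = "numeric"))

setValidity("KinshipMatrix", function(object) {
  K <- object@K
  msg <- character()
  if (nrow(K) != ncol(K)) msg <- c(msg, "K must be square")
  if (is.null(rownames(K)) || !identical(rownames(K), colnames(K)))
    msg <- c(msg, "K must carry matching accession dimnames")
  if (max(abs(K - t(K))) >= 1e-10)
    msg <- c(msg, "K must be symmetric to within 1e-10")
  if (length(msg)) msg else TRUE
})

## ---- generics -------------------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @param object,x a GenotypeMatrix or KinshipMatrix
#' @export
setGeneric("accessionIds", function(object) standardGeneric("accessionIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("callMatrix", function(object) standardGeneric("callMatrix"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerInfo", function(object) standardGeneric("markerInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nAccessions", function(object) standardGeneric("nAccessions"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nMarkers", function(object) standardGeneric("nMarkers"))

#' @rdname KinshipMatrix-class
#' @export
setGeneric("kinship", function(object) standardGeneric("kinship"))

#' @rdname KinshipMatrix-class
#' @export
setGeneric("kinshipRidge", function(object) standardGeneric("kinshipRidge"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("accessionIds", "GenotypeMatrix",
          function(object) rownames(object@calls))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("callMatrix", "GenotypeMatrix", function(object) object@calls)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(object) object@markers)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nAccessions", "GenotypeMatrix",
          function(object) nrow(object@calls))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(object) ncol(object@calls))

#' @rdname KinshipMatrix-class
#' @export
setMethod("accessionIds", "KinshipMatrix",
          function(object) rownames(object@K))

#' @rdname KinshipMatrix-class
#' @export
setMethod("kinship", "KinshipMatrix", function(object) object@K)

#' @rdname KinshipMatrix-class
#' @export
setMethod("kinshipRidge", "KinshipMatrix", function(object) object@ridge)

#' @rdname GenotypeMatrix-class
#' @param i,j,drop row (accession) / column (marker) indices; drop ignored
#' @param ... unused
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls
  mk <- x@markers
  if (!missing(i)) calls <- calls[i, , drop = FALSE]
  if (!missing(j)) {
    calls <- calls[, j, drop = FALSE]
    mk <- mk[j]
  }
  new("GenotypeMatrix", calls = calls, markers = mk)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d accessions x %d markers (0/1 inbred coding)\n",
              nrow(object@calls), ncol(object@calls)))
  chr <- as.character(GenomicRanges::seqnames(object@markers))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(chr), collapse = ", ")))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d accessions, estimator = %s",
              nrow(object@K), object@estimator))
  if (object@ridge > 0)
    cat(sprintf(", ridge = %.3g", object@ridge))
  cat("\n")
})
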