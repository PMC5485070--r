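## Genotype, geography and phenotype table I/O.
##
## Text dialect: a genotype TSV (accessions x markers, header = marker ids,
## first column = accession id) plus a marker sidecar TSV with columns
## (marker_id, chromosome, position_bp_1based).  PLINK .bed/.bim/.fam is
## accepted as an alternative; being an inbred panel, only homozygous
## genotypes are allowed and they map to {0, 1}.

#' Read a genotype matrix
#'
#' @param path path to the genotype TSV (for \code{format = "tsv"}) or to
#'   any of the three PLINK files / their common prefix (for
#'   \code{format = "plink"}).
#' @param format \code{"tsv"} or \code{"plink"}.
#' @param markers for \code{"tsv"}, path to the marker sidecar TSV with
#'   columns \code{marker_id}, \code{chromosome}, \code{position_bp_1based}.
#'   Defaults to \code{<path>.markers.tsv}.
#' @return A validated \linkS4class{GenotypeMatrix} with markers sorted by
#'   (chromosome, position).
#' @details Calls other than 0/1 (missing, heterozygous, diploid dosage 2)
#'   are a validation error, never silently imputed or rescaled.
#' @examples
#' g <- simulateGenotypesIbd(simulationTruth(n_accessions = 12,
#'                                           n_markers = 40, seed = 1))$geno
#' tf <- tempfile(fileext = ".tsv")
#' writeGenotypes(g, tf)
#' g2 <- readGenotypes(tf)
#' stopifnot(identical(callMatrix(g), callMatrix(g2)))
#' @export
readGenotypes <- function(path, format = c("tsv", "plink"),
                          markers = paste0(path, ".markers.tsv")) {
  format <- match.arg(format)
  if (format == "plink") return(readPlink(path))
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (!file.exists(markers)) stop("marker sidecar file not found: ", markers)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("malformed genotype TSV (need id column + markers): ", path)
  ids <- tab[[1]]
  calls <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "double")
  bad <- which(is.na(calls) | (calls != 0 & calls != 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-{0,1} genotype call for accession '%s', marker '%s' (record %d)",
      ids[bad[1, 1]], colnames(calls)[bad[1, 2]], bad[1, 1]))
  }
  rownames(calls) <- ids
  side <- utils::read.table(markers, header = TRUE, sep = "\t",
                            check.names = FALSE)
  need <- c("marker_id", "chromosome", "position_bp_1based")
  if (!all(need %in% names(side)))
    stop("marker sidecar must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(colnames(calls), as.character(side$marker_id))
  if (length(miss))
    stop("markers missing from sidecar: ", paste(utils::head(miss, 5), collapse = ", "))
  side <- side[match(colnames(calls), as.character(side$marker_id)), ]
  GenotypeMatrix(calls, side$chromosome, side$position_bp_1based)
}

#' Write a genotype matrix as TSV plus marker sidecar
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param path output TSV path; the sidecar goes to
#'   \code{<path>.markers.tsv}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(geno, path) {
  stopifnot(is(geno, "GenotypeMatrix"))
  calls <- callMatrix(geno)
  df <- data.frame(accession_id = rownames(calls), calls,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- markerInfo(geno)
  side <- data.frame(marker_id = names(mk),
                     chromosome = as.character(GenomicRanges::seqnames(mk)),
                     position_bp_1based = GenomicRanges::start(mk))
  utils::write.table(side, paste0(path, ".markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

plinkPrefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' SNP-major .bed files only.  Genotype codes: homozygous A1 -> 1 dose of
#' the A1 allele... concretely the two homozygote codes map to 0 and 1;
#' heterozygous or missing codes are an error (inbred panel contract).
#'
#' @param path prefix or any of the .bed/.bim/.fam paths.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readPlink <- function(path) {
  prefix <- plinkPrefix(path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  famt <- utils::read.table(fam, header = FALSE,
                            colClasses = "character")
  ids <- famt[[2]]
  bimt <- utils::read.table(bim, header = FALSE,
                            colClasses = c("character", "character",
                                           "numeric", "integer",
                                           "character", "character"))
  n <- length(ids); m <- nrow(bimt)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bpm <- ceiling(n / 4)                      # bytes per marker
  body <- raw[-(1:3)]
  if (length(body) != bpm * m)
    stop(sprintf(".bed payload size mismatch (%d bytes for %d x %d)",
                 length(body), n, m))
  ## unpack 2-bit genotypes, sample-fastest within marker
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[seq(1, 8, 2), , drop = FALSE] +
    2L * bits[seq(2, 8, 2), , drop = FALSE]        # 4 samples per byte
  codes <- matrix(as.vector(codes), nrow = 4 * bpm)[seq_len(n), , drop = FALSE]
  ## PLINK codes: 0 = hom A1, 2 = het (01 pattern -> 1), 3 = hom A2, 1 = missing
  ## rawToBits order gives value b1 + 2*b2: 00->0 homA1, 10->1 missing,
  ## 01->2 het, 11->3 homA2
  if (any(codes == 1L))
    stop("missing genotype call in .bed (not supported for inbred panels)")
  if (any(codes == 2L))
    stop("heterozygous genotype call in .bed (not supported for inbred panels)")
  calls <- matrix(0, n, m, dimnames = list(ids, bimt[[2]]))
  calls[codes == 0L] <- 1        # hom A1 = carries counted (minor) allele
  GenotypeMatrix(calls, bimt[[1]], bimt[[4]])
}

#' Write PLINK .bed/.bim/.fam genotypes
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(geno, prefix) {
  stopifnot(is(geno, "GenotypeMatrix"))
  calls <- callMatrix(geno)
  n <- nrow(calls); m <- ncol(calls)
  mk <- markerInfo(geno)
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(mk)), names(mk), 0,
               GenomicRanges::start(mk), "A", "T"),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(rownames(calls), rownames(calls), 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ## 1 -> code 0 (hom A1), 0 -> code 3 (hom A2)
  codes <- ifelse(calls == 1, 0L, 3L)
  bpm <- ceiling(n / 4)
  pad <- matrix(0L, 4 * bpm - n, m)
  codes <- rbind(codes, pad)
  b1 <- codes %% 2L; b2 <- codes %/% 2L
  bits <- matrix(0L, 8, bpm * m)
  bits[seq(1, 8, 2), ] <- matrix(as.vector(b1), nrow = 4)
  bits[seq(2, 8, 2), ] <- matrix(as.vector(b2), nrow = 4)
  payload <- packBits(as.logical(bits), type = "raw")
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), payload), paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read a geographic table
#'
#' CSV with columns \code{accession_id}, \code{latitude}, \code{longitude},
#' \code{elevation} (degrees, degrees, metres).
#'
#' @param path CSV path.
#' @return data.frame with the four columns, validated.
#' @export
readGeoTable <- function(path) {
  geo <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "latitude", "longitude", "elevation")
  if (!all(need %in% names(geo)))
    stop("geographic table must have columns: ", paste(need, collapse = ", "))
  validateGeoTable(geo[need])
}

validateGeoTable <- function(geo) {
  if (any(geo$latitude < -90 | geo$latitude > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(geo$longitude < -180 | geo$longitude > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  if (anyDuplicated(geo$accession_id))
    stop("duplicate accession_id in geographic table")
  geo
}
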