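## End-to-end orchestration: simulate/ingest -> kinship -> structure ->
## responses -> heritability -> animal models -> MTMM -> QTL report.

#' Pipeline configuration
#'
#' Defaults follow the published analysis settings: structure alpha
#' 0.001 with ten genetic groups and k = 5 nearest-neighbour spatial
#' weights, the 75-day life-cycle threshold, MCMC 150,000/50/50,000 for
#' the Gaussian models and ten-fold longer for the threshold model, MAF
#' 0.05, -log10(p) threshold 4 and a 20-kb QTL window.
#'
#' @param simulate a [simulationTruth()] to generate inputs, or NULL to
#'   read files.
#' @param genotypes,geo,bioassay,flowering input paths (used when
#'   \code{simulate} is NULL): genotype TSV, geographic CSV, a list of
#'   four bioassay CSVs, and a flowering-time CSV.
#' @param kinship_estimator \code{"standardized"} or \code{"ibs"}.
#' @param alpha,n_groups,weights_k structure-stage parameters.
#' @param life_cycle_threshold days (winter iff >= threshold).
#' @param mcmc_gaussian,mcmc_threshold [mcmcSettings()] for model types
#'   1/3 and type 2.
#' @param maf,qtl_threshold,window_bp MTMM-stage parameters.
#' @param seed master seed (propagated to every stochastic stage).
#' @param out_dir output directory.
#' @return list of class \code{"stresshap_config"}.
#' @export
pipelineConfig <- function(simulate = simulationTruth(),
                           genotypes = NULL, geo = NULL, bioassay = NULL,
                           flowering = NULL,
                           kinship_estimator = "standardized",
                           alpha = 0.001, n_groups = 10, weights_k = 5,
                           life_cycle_threshold = 75,
                           mcmc_gaussian = mcmcSettings(150000, 50, 50000),
                           mcmc_threshold = mcmcSettings(1500000, 500,
                                                         500000),
                           maf = 0.05, qtl_threshold = 4,
                           window_bp = 20000, seed = 7,
                           out_dir = tempfile("stresshap_run_")) {
  stopifnot(inherits(mcmc_gaussian, "stresshap_mcmc"),
            inherits(mcmc_threshold, "stresshap_mcmc"))
  if (is.null(simulate)) {
    for (p in c(genotypes, geo, unlist(bioassay), flowering))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(as.list(environment()), class = "stresshap_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override the [pipelineConfig()] defaults; MCMC blocks
#' are given as \code{mcmc_gaussian: {n_iter, thin, burn_in, seed}}.
#'
#' @param path YAML file.
#' @return list of class \code{"stresshap_config"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("kinship_estimator", "alpha", "n_groups", "weights_k",
               "life_cycle_threshold", "maf", "qtl_threshold",
               "window_bp", "seed", "out_dir", "genotypes", "geo",
               "flowering"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$bioassay)) args$bioassay <- as.list(y$bioassay)
  for (nm in c("mcmc_gaussian", "mcmc_threshold"))
    if (!is.null(y[[nm]]))
      args[[nm]] <- do.call(mcmcSettings, y[[nm]])
  if (isTRUE(y$read_inputs)) args$simulate <- NULL
  else if (!is.null(y$simulate))
    args$simulate <- do.call(simulationTruth, y$simulate)
  do.call(pipelineConfig, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order and writes the report
#' bundle: \code{groups.csv} (+ \code{ward.newick} when \pkg{ape} is
#' available), \code{responses.csv}, \code{h2_table.csv},
#' \code{animal_type1.csv} / \code{animal_type2.csv} /
#' \code{animal_type3.csv}, \code{mtmm_results.tsv},
#' \code{qtl_regions.bed} (0-based half-open) and
#' \code{provenance.yaml}.  Any stage failure halts with the stage name
#' and the path of the last good artifact.
#'
#' @param config a [pipelineConfig()] (or a YAML path).
#' @return invisibly, a list with every stage result and
#'   \code{out_dir}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "stresshap_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  last_good <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (last good artifact: %s)",
                   name, conditionMessage(e),
                   if (is.null(last_good)) "none" else last_good),
           call. = FALSE))
  }
  res <- list(out_dir = config$out_dir)
  out <- function(f) file.path(config$out_dir, f)

  res$data <- stage("data", {
    if (!is.null(config$simulate)) {
      sim <- simulateGenotypesIbd(config$simulate)
      ph <- simulatePhenotypes(sim$geno, sim$geo, config$simulate)
      list(geno = sim$geno, geo = sim$geo, bioassay = ph$bioassay,
           flowering = ph$flowering, truth = ph)
    } else {
      list(geno = readGenotypes(config$genotypes),
           geo = readGeoTable(config$geo),
           bioassay = lapply(config$bioassay, utils::read.csv),
           flowering = utils::read.csv(config$flowering))
    }
  })
  res$kinship <- stage("kinship", {
    K <- computeKinship(res$data$geno, config$kinship_estimator)
    writeKinship(K, out("kinship.tsv")); last_good <<- out("kinship.tsv")
    K
  })
  res$structure <- stage("structure", {
    pca <- pcaMarkers(res$data$geno,
                      min(20, nAccessions(res$data$geno) - 1))
    w <- buildSpatialWeights(res$data$geo, "knn", k = config$weights_k)
    sel <- selectInformativePcs(pca, w, alpha = config$alpha)
    ret <- if (length(sel$retained)) sel$retained else 1L
    groups <- wardCluster(pca$scores[, ret, drop = FALSE],
                          config$n_groups)
    utils::write.csv(data.frame(accession_id = names(groups$assignment),
                                group = groups$assignment),
                     out("groups.csv"), row.names = FALSE)
    if (requireNamespace("ape", quietly = TRUE))
      ape::write.tree(ape::as.phylo(groups$hclust), out("ward.newick"))
    last_good <<- out("groups.csv")
    list(pca = pca, weights = w, informative = sel, groups = groups)
  })
  res$responses <- stage("responses", {
    fits <- lapply(1:4, function(e)
      fitExperimentLmm(res$data$bioassay[[e]], e))
    means <- lapply(fits, predictedMeans)
    resp <- deriveStressResponses(means[[1]], means[[2]], means[[3]],
                                  means[[4]])
    lc <- classifyLifeCycle(res$data$flowering,
                            config$life_cycle_threshold)
    utils::write.csv(resp, out("responses.csv"), row.names = FALSE)
    last_good <<- out("responses.csv")
    list(fits = fits, responses = resp, life_cycle = lc)
  })
  res$h2 <- stage("heritability", {
    tab <- h2Table(res$responses$responses, res$kinship)
    utils::write.csv(tab, out("h2_table.csv"), row.names = FALSE)
    last_good <<- out("h2_table.csv")
    tab
  })
  res$animal <- stage("animal_models", {
    lc <- res$responses$life_cycle
    t1 <- stressGradientModels(res$responses$responses, lc,
                               res$data$geo, res$kinship,
                               mcmc = config$mcmc_gaussian)
    utils::write.csv(attr(t1, "table"), out("animal_type1.csv"),
                     row.names = FALSE)
    gi <- match(lc$accession_id, res$data$geo$accession_id)
    X2 <- cbind(elevation = res$data$geo$elevation[gi],
                latitude = res$data$geo$latitude[gi],
                longitude = res$data$geo$longitude[gi])
    rownames(X2) <- lc$accession_id
    lab <- stats::setNames(as.numeric(lc$strategy == "winter"),
                           lc$accession_id)
    t2 <- fitThresholdAnimalModel(lab, X2, res$kinship,
                                  mcmc = config$mcmc_threshold)
    utils::write.csv(cbind(response = "Flowering type", t2$fixed),
                     out("animal_type2.csv"), row.names = FALSE)
    t3 <- tradeOffModels(res$responses$responses, lc, res$kinship,
                         mcmc = config$mcmc_gaussian)
    utils::write.csv(attr(t3, "table"), out("animal_type3.csv"),
                     row.names = FALSE)
    last_good <<- out("animal_type3.csv")
    list(type1 = t1, type2 = t2, type3 = t3)
  })
  res$mtmm <- stage("mtmm", {
    tv <- buildTraitVectors(res$responses$responses)
    fit <- fitMtmmVarcomp(tv$p1, tv$p2, res$kinship)
    tests <- glsFTests(res$data$geno, fit, tv$p1, tv$p2,
                       maf_min = config$maf)
    utils::write.table(tests, out("mtmm_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    regions <- selectQtlRegions(tests, "specific",
                                config$qtl_threshold, config$window_bp)
    writeRegionsBed(regions, out("qtl_regions.bed"))
    last_good <<- out("mtmm_results.tsv")
    list(traits = tv, fit = fit, tests = tests, regions = regions)
  })
  stage("provenance", {
    prov <- list(
      package = "stresshap",
      version = as.character(utils::packageVersion("stresshap")),
      seed = config$seed,
      n_accessions = nAccessions(res$data$geno),
      n_markers = nMarkers(res$data$geno),
      kinship_estimator = config$kinship_estimator,
      kinship_ridge = kinshipRidge(res$kinship),
      informative_pcs = length(res$structure$informative$retained),
      config_hash = configHash(config))
    yaml::write_yaml(prov, out("provenance.yaml"))
  })
  invisible(res)
}

configHash <- function(config) {
  scalars <- Filter(function(x) is.atomic(x) || inherits(x, "stresshap_mcmc"),
                    unclass(config))
  txt <- paste(utils::capture.output(utils::str(scalars)), collapse = "\n")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Write QTL regions as a BED file
#'
#' Converts the internal 1-based inclusive regions to BED's 0-based
#' half-open convention (start - 1, end).
#'
#' @param regions GRanges from [selectQtlRegions()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  if (length(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = paste0("QTL", S4Vectors::mcols(regions)$region),
    score = round(S4Vectors::mcols(regions)$peak_neg_log10, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
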