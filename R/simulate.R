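## Synthetic-data generator with known ground truth.
##
## Genotypes follow an isolation-by-distance model: demes on a 2-D map
## whose allele frequencies drift from a common ancestral frequency with
## spatially correlated deviations, accessions drawn Bernoulli from
## their deme frequencies (haploid 0/1, inbred lines).  Phenotypes are
## additive-genetic draws under the realized kinship with per-trait
## heritability, life-cycle fixed effects and genetic correlations, and
## are unfolded into per-plant bioassay tables through the designed
## block/positional structure.

stressTraits <- c("Drought", "P_rapae", "Drought_Pieris",
                  "Botrytis_Pieris", "P_xylostella", "F_occidentalis",
                  "M_persicae")

#' Ground-truth parameters for the synthetic study
#'
#' Defaults emulate the study conditions of the European accession
#' panel: 308 accessions, ten-ish recoverable genetic groups, trait
#' means/heritabilities/variances on the scale of the published summary
#' table, the published winter-vs-summer effect sizes, the published
#' trade-off signs (drought vs P. rapae, P. rapae vs M. persicae), and
#' a winter-annual fraction near 89/308 driven by high latitude and low
#' elevation.
#'
#' @param n_accessions,n_markers panel size (defaults 308 x 3000; the
#'   marker count is a desk-scale stand-in for a dense SNP set).
#' @param n_demes,drift_scale,drift_range IBD structure: demes on the
#'   European lon/lat window, logit-scale drift with sd
#'   \code{drift_scale} and exponential spatial correlation range
#'   \code{drift_range} (degrees).
#' @param h2 named per-trait narrow-sense heritability.
#' @param trait_mean,trait_var named per-trait means and total
#'   (va + ve) variances on the response scale.
#' @param life_cycle_effect named winter-minus-summer fixed effects.
#' @param genetic_cor 7 x 7 genetic correlation matrix (PSD).
#' @param winter_fraction target winter-annual proportion.
#' @param lc_latitude,lc_elevation,lc_h2 probit coefficients (per SD of
#'   latitude / elevation) and liability heritability of the life-cycle
#'   label: winter annuals concentrate at high latitude and low
#'   elevation.
#' @param block_var,position_var,residual_var bioassay variance
#'   components: temporal-block, positional (rack/shelf/tray/x/y share
#'   this), and per-plant residual, on the measurement scale.
#' @param reps per-experiment replicate counts (exp2/exp3 replicates
#'   equal their block counts by design).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline rosette
#'   fresh weight (g); percentage responses are scale-free in it.
#' @param seed RNG seed; all generator randomness derives from it.
#' @return list of class \code{"stresshap_truth"}.
#' @export
simulationTruth <- function(n_accessions = 308, n_markers = 3000,
                            n_demes = 10, drift_scale = 1.5,
                            drift_range = 12,
                            h2 = c(Drought = 0.41, P_rapae = 0.60,
                                   Drought_Pieris = 0.39,
                                   Botrytis_Pieris = 0.67,
                                   P_xylostella = 0.25,
                                   F_occidentalis = 0.90,
                                   M_persicae = 0.34),
                            trait_mean = c(Drought = 19.22, P_rapae = 32.40,
                                           Drought_Pieris = 48.25,
                                           Botrytis_Pieris = 14.42,
                                           P_xylostella = 14.15,
                                           F_occidentalis = 21.98,
                                           M_persicae = 27.89),
                            trait_var = c(Drought = 203.28, P_rapae = 191.51,
                                          Drought_Pieris = 249.67,
                                          Botrytis_Pieris = 286.24,
                                          P_xylostella = 381.33,
                                          F_occidentalis = 85.74,
                                          M_persicae = 31.15),
                            life_cycle_effect = c(Drought = -9.21,
                                                  P_rapae = 4.61,
                                                  Drought_Pieris = 7.37,
                                                  Botrytis_Pieris = 10.68,
                                                  P_xylostella = 10.40,
                                                  F_occidentalis = -3.50,
                                                  M_persicae = -1.75),
                            genetic_cor = NULL,
                            winter_fraction = 89 / 308,
                            lc_latitude = 1.2, lc_elevation = -0.8,
                            lc_h2 = 0.3,
                            block_var = 2, position_var = 0.5,
                            residual_var = 1,
                            reps = c(exp1 = 6, exp2 = 4, exp3 = 5,
                                     exp4 = 3),
                            baseline_meanlog = log(10),
                            baseline_sdlog = 0.1,
                            seed = 7) {
  if (n_accessions < 10 || n_markers < 100)
    stop("need n_accessions >= 10 and n_markers >= 100")
  if (is.null(genetic_cor)) {
    genetic_cor <- diag(7)
    dimnames(genetic_cor) <- list(stressTraits, stressTraits)
    genetic_cor["Drought", "P_rapae"] <-
      genetic_cor["P_rapae", "Drought"] <- -0.5
    genetic_cor["P_rapae", "M_persicae"] <-
      genetic_cor["M_persicae", "P_rapae"] <- -0.5
  }
  stopifnot(all(h2 >= 0 & h2 <= 1), all(trait_var > 0),
            identical(dim(genetic_cor), c(7L, 7L)))
  if (min(eigen(genetic_cor, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("genetic correlation matrix must be positive semi-definite")
  structure(list(n_accessions = n_accessions, n_markers = n_markers,
                 n_demes = n_demes, drift_scale = drift_scale,
                 drift_range = drift_range, h2 = h2[stressTraits],
                 trait_mean = trait_mean[stressTraits],
                 trait_var = trait_var[stressTraits],
                 life_cycle_effect = life_cycle_effect[stressTraits],
                 genetic_cor = genetic_cor,
                 winter_fraction = winter_fraction,
                 lc_latitude = lc_latitude, lc_elevation = lc_elevation,
                 lc_h2 = lc_h2, block_var = block_var,
                 position_var = position_var,
                 residual_var = residual_var, reps = reps,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, seed = seed),
            class = "stresshap_truth")
}

#' Simulate genotypes with isolation-by-distance structure
#'
#' @param truth a [simulationTruth()].
#' @return list with \code{geno} (\linkS4class{GenotypeMatrix}),
#'   \code{geo} (accession_id, latitude, longitude, elevation),
#'   \code{deme} (integer assignment).  Markers that come out
#'   monomorphic are dropped (so the realized marker count can be
#'   slightly below \code{n_markers}); ten chromosomes of equal marker
#'   share with positions on a 1 kb grid.
#' @export
simulateGenotypesIbd <- function(truth) {
  stopifnot(inherits(truth, "stresshap_truth"))
  withSeed(truth$seed, {
    n <- truth$n_accessions; m <- truth$n_markers; d <- truth$n_demes
    ## demes on a European-like lon/lat window
    deme_lon <- stats::runif(d, -10, 40)
    deme_lat <- stats::runif(d, 35, 62)
    D <- as.matrix(stats::dist(cbind(deme_lon, deme_lat)))
    Sig <- truth$drift_scale^2 * exp(-D / truth$drift_range)
    L <- chol(Sig + diag(1e-8, d))
    p0 <- stats::runif(m, 0.1, 0.9)
    drift <- crossprod(L, matrix(stats::rnorm(d * m), d, m))
    pf <- stats::plogis(stats::qlogis(p0)[col(drift)] + drift)
    deme <- rep(seq_len(d), length.out = n)
    calls <- matrix(stats::rbinom(n * m, 1, pf[deme, ]), n, m)
    ids <- sprintf("acc%03d", seq_len(n))
    rownames(calls) <- ids
    poly <- colMeans(calls) > 0 & colMeans(calls) < 1
    calls <- calls[, poly, drop = FALSE]
    mkeep <- ncol(calls)
    chrom <- rep(as.character(1:10), length.out = mkeep)
    pos <- integer(mkeep)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      pos[idx] <- seq_along(idx) * 1000L
    }
    colnames(calls) <- sprintf("chr%s_%d", chrom, pos)
    geno <- GenotypeMatrix(calls, chrom, pos)
    geo <- data.frame(
      accession_id = ids,
      latitude = deme_lat[deme] + stats::rnorm(n, 0, 1.5),
      longitude = deme_lon[deme] + stats::rnorm(n, 0, 1.5),
      elevation = pmax(0, stats::rnorm(n, 500, 350)))
    list(geno = geno, geo = geo, deme = deme)
  })
}

## eigen-based PSD square root (K is typically singular)
psdSqrt <- function(K) {
  eg <- eigen(K, symmetric = TRUE)
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Simulate phenotypes, life cycle and bioassay tables
#'
#' Draws additive genetic values \eqn{G \sim N(0, V_g \otimes K)} for
#' the seven stresses under the realized standardized kinship, builds
#' the winter/summer label from a latitude/elevation probit with a
#' heritable liability component, adds the winter-vs-summer fixed
#' effects and residual noise, and unfolds each response into the
#' per-plant bioassay design by inverting the percentage-reduction
#' definition around a log-normal baseline weight, with
#' block/positional random effects and residual noise.
#'
#' @param geno,geo output of [simulateGenotypesIbd()].
#' @param truth the same [simulationTruth()].
#' @return list with \code{bioassay} (list of four per-plant
#'   data.frames), \code{flowering} (accession_id,
#'   flowering_time_days, flowering_time_after_vernalization_days,
#'   censored), \code{life_cycle} (classification at the 75-day
#'   threshold), \code{responses_true} (per-accession ground-truth
#'   StressResponseTable), \code{genetic_values} (n x 7 matrix),
#'   \code{K} (the realized \linkS4class{KinshipMatrix}).
#' @export
simulatePhenotypes <- function(geno, geo, truth) {
  stopifnot(inherits(truth, "stresshap_truth"))
  K <- computeKinship(geno, "standardized")
  n <- nAccessions(geno)
  ids <- accessionIds(geno)
  withSeed(truth$seed + 1L, {
    Lk <- psdSqrt(kinship(K))
    sd_g <- sqrt(truth$h2 * truth$trait_var)
    Vg <- diag(sd_g) %*% truth$genetic_cor %*% diag(sd_g)
    Lv <- chol(Vg + diag(1e-10, 7))
    G <- Lk %*% matrix(stats::rnorm(n * 7), n, 7) %*% Lv
    colnames(G) <- stressTraits
    rownames(G) <- ids

    ## life-cycle label: probit on standardized latitude/elevation with
    ## a kinship-structured liability component
    g_lc <- drop(Lk %*% stats::rnorm(n)) * sqrt(truth$lc_h2)
    env_lc <- truth$lc_latitude * drop(scale(geo$latitude)) +
      truth$lc_elevation * drop(scale(geo$elevation))
    noise_lc <- stats::rnorm(n) * sqrt(1 - truth$lc_h2)
    raw <- env_lc + g_lc + noise_lc
    ## centre the liability so the winter fraction matches the target
    liab <- raw - stats::quantile(raw, 1 - truth$winter_fraction)
    winter <- liab > 0
    flowering <- data.frame(
      accession_id = ids,
      flowering_time_days = pmin(75 + 25 * liab, 200),
      flowering_time_after_vernalization_days = stats::runif(n, 20, 40),
      censored = liab > 3)
    ## never-flowered accessions carry a censored flag; their recorded
    ## time stays >= 75 so the threshold rule is unaffected

    sd_e <- sqrt((1 - truth$h2) * truth$trait_var)
    E <- matrix(stats::rnorm(n * 7), n, 7) %*% diag(sd_e)
    R <- matrix(truth$trait_mean, n, 7, byrow = TRUE) +
      outer(as.numeric(winter), truth$life_cycle_effect) + G + E
    colnames(R) <- stressTraits
    responses_true <- data.frame(accession_id = ids, R, row.names = NULL)

    ## accession cell-mean weights for experiments 1-2
    W0 <- stats::rlnorm(n, truth$baseline_meanlog, truth$baseline_sdlog)
    Wcell <- cbind(
      control = W0,
      drought = W0 * (1 - R[, "Drought"] / 100),
      p_rapae = W0 * (1 - R[, "P_rapae"] / 100),
      drought_pieris = W0 * (1 - R[, "Drought"] / 100) *
        (1 - R[, "Drought_Pieris"] / 100),
      botrytis_pieris = W0 * (1 - R[, "Botrytis_Pieris"] / 100))
    W0_2 <- stats::rlnorm(n, truth$baseline_meanlog, truth$baseline_sdlog)
    Wcell2 <- cbind(control = W0_2,
                    p_xylostella = W0_2 * (1 - R[, "P_xylostella"] / 100))

    sdb <- sqrt(truth$block_var)
    sdp <- sqrt(truth$position_var)
    sdr <- sqrt(truth$residual_var)
    ranef <- function(labels, sd) {
      lev <- unique(labels)
      stats::setNames(stats::rnorm(length(lev), 0, sd), lev)[labels]
    }

    ## experiment 1: accessions in 10 temporal blocks, 6 racks x 4
    ## shelves, trays of 20, x in 1..5, y in 1..4
    n_blocks1 <- max(2, min(10, ceiling(n / 5)))
    block1 <- rep(seq_len(n_blocks1), length.out = n)  # accession -> block
    ## three check accessions recur in every temporal block (one plant
    ## per treatment per block) to connect blocks to the genotype cells
    checks <- seq_len(min(3, n))
    grid1 <- expand.grid(accession = setdiff(seq_len(n), checks),
                         treatment = colnames(Wcell),
                         rep = seq_len(truth$reps[["exp1"]]),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid1$block <- block1[grid1$accession]
    gridc <- expand.grid(accession = checks,
                         treatment = colnames(Wcell),
                         block = seq_len(n_blocks1),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gridc$rep <- 1L
    grid1 <- rbind(grid1, gridc[names(grid1)])
    b1 <- data.frame(
      plant_id = sprintf("e1_%05d", seq_len(nrow(grid1))),
      accession_id = ids[grid1$accession],
      treatment = grid1$treatment,
      block = grid1$block, stringsAsFactors = FALSE)
    ord <- order(b1$block)
    b1 <- b1[ord, ]; grid1 <- grid1[ord, ]
    slot <- stats::ave(seq_len(nrow(b1)), b1$block, FUN = seq_along) - 1
    b1$rack <- slot %/% (4 * 20) %% 6 + 1
    b1$shelf <- slot %/% 20 %% 4 + 1
    b1$tray <- slot %/% 20 + 1
    b1$x <- slot %% 5 + 1
    b1$y <- slot %/% 5 %% 4 + 1
    cell1 <- Wcell[cbind(grid1$accession, match(grid1$treatment,
                                                colnames(Wcell)))]
    brs <- paste(b1$block, b1$rack, b1$shelf)
    brst <- paste(brs, b1$tray)
    b1$value <- cell1 +
      ranef(b1$block, sdb) + ranef(b1$rack, sdp) + ranef(b1$shelf, sdp) +
      ranef(brs, sdp) + ranef(brst, sdp) +
      ranef(paste(brst, b1$x), sdp) + ranef(paste(brst, b1$y), sdp) +
      stats::rnorm(nrow(b1), 0, sdr)

    ## experiment 2: every accession once per temporal block (block =
    ## replicate), 40 trays per block
    n_blocks2 <- truth$reps[["exp2"]]
    grid2 <- expand.grid(accession = seq_len(n),
                         treatment = colnames(Wcell2),
                         block = seq_len(n_blocks2),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    b2 <- data.frame(
      plant_id = sprintf("e2_%05d", seq_len(nrow(grid2))),
      accession_id = ids[grid2$accession],
      treatment = grid2$treatment,
      block = grid2$block, stringsAsFactors = FALSE)
    slot2 <- stats::ave(seq_len(nrow(b2)), b2$block, FUN = seq_along) - 1
    b2$tray <- slot2 %/% 16 %% 40 + 1
    b2$x <- slot2 %% 4 + 1
    b2$y <- slot2 %/% 4 %% 4 + 1
    cell2 <- Wcell2[cbind(grid2$accession, match(grid2$treatment,
                                                 colnames(Wcell2)))]
    bt <- paste(b2$block, b2$tray)
    b2$value <- cell2 + ranef(b2$block, sdb) + ranef(bt, sdp) +
      ranef(paste(bt, b2$x), sdp) + ranef(paste(bt, b2$y), sdp) +
      stats::rnorm(nrow(b2), 0, sdr)

    ## experiments 3-4: block/sub-block designs on the response scale
    simBlocked <- function(trait, n_blocks, n_sub, prefix) {
      grid <- expand.grid(accession = seq_len(n),
                          block = seq_len(n_blocks),
                          KEEP.OUT.ATTRS = FALSE)
      b <- data.frame(
        plant_id = sprintf("%s_%05d", prefix, seq_len(nrow(grid))),
        accession_id = ids[grid$accession],
        block = grid$block,
        sub_block = grid$accession %% n_sub + 1,
        stringsAsFactors = FALSE)
      bs <- paste(b$block, b$sub_block)
      b$value <- R[grid$accession, trait] + ranef(b$block, sdb) +
        ranef(bs, sdp) + stats::rnorm(nrow(b), 0, sdr)
      b
    }
    b3 <- simBlocked("F_occidentalis", truth$reps[["exp3"]], 2, "e3")
    b4 <- simBlocked("M_persicae", truth$reps[["exp4"]], 4, "e4")

    list(bioassay = list(exp1 = b1, exp2 = b2, exp3 = b3, exp4 = b4),
         flowering = flowering,
         life_cycle = classifyLifeCycle(flowering),
         responses_true = responses_true,
         genetic_values = G, K = K)
  })
}
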