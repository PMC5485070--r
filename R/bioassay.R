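## Per-plant bioassay mixed models, genotypic predicted means, derived
## stress-response variables and winter/summer life-cycle classification.
##
## Experiment layouts (fresh weight g unless noted):
##   1  five treatments (control, drought, p_rapae, drought_pieris,
##      botrytis_pieris); random terms B, R, S, B:R:S, B:R:S:T,
##      B:R:S:T:X, B:R:S:T:Y
##   2  two treatments (control, p_xylostella); random B, B:T, B:T:X, B:T:Y
##   3  thrips silver damage, mm2; no treatment factor; random B, B:SB
##   4  aphid count; no treatment factor; random B, B:SB

#' Treatment vocabulary per experiment
#' @keywords internal
experimentTreatments <- function(experiment) {
  switch(as.character(experiment),
    "1" = c("control", "drought", "p_rapae", "drought_pieris",
            "botrytis_pieris"),
    "2" = c("control", "p_xylostella"),
    "3" = ,
    "4" = character(0),
    stop("experiment must be 1, 2, 3 or 4"))
}

experimentRandomTerms <- function(experiment) {
  switch(as.character(experiment),
    "1" = c("(1 | block)", "(1 | rack)", "(1 | shelf)",
            "(1 | block:rack:shelf)", "(1 | block:rack:shelf:tray)",
            "(1 | block:rack:shelf:tray:x)",
            "(1 | block:rack:shelf:tray:y)"),
    "2" = c("(1 | block)", "(1 | block:tray)", "(1 | block:tray:x)",
            "(1 | block:tray:y)"),
    "3" = ,
    "4" = c("(1 | block)", "(1 | block:sub_block)"))
}

#' Fit the experiment-specific linear mixed model on per-plant data
#'
#' REML fit of the experiment's fixed structure (GEN + TRT + GEN x TRT
#' for experiments 1-2; GEN only for 3-4) with independent variance
#' components for the design's temporal/positional random terms.
#'
#' @param data data.frame with columns \code{accession_id},
#'   \code{value} and the positional factors the experiment requires
#'   (\code{treatment}, \code{block}, \code{sub_block}, \code{rack},
#'   \code{shelf}, \code{tray}, \code{x}, \code{y}); all factors are
#'   treated as categorical.
#' @param experiment 1, 2, 3 or 4.
#' @return list of class \code{"stresshap_lmm"}: \code{fit} (the
#'   \pkg{lme4} model), \code{experiment}, \code{fixed} (estimates and
#'   standard errors), \code{varcomp} (named variance components incl.
#'   \code{residual}), \code{reml_loglik}, \code{has_treatment}.
#' @export
fitExperimentLmm <- function(data, experiment) {
  experiment <- as.integer(experiment)
  trts <- experimentTreatments(experiment)
  has_trt <- length(trts) > 0
  need <- c("accession_id", "value",
            if (has_trt) "treatment",
            switch(experiment, c("block", "rack", "shelf", "tray", "x", "y"),
                   c("block", "tray", "x", "y"),
                   c("block", "sub_block"), c("block", "sub_block")))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("bioassay table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(data$value))) stop("non-finite bioassay values")
  d <- data
  for (col in setdiff(need, "value")) d[[col]] <- factor(d[[col]])
  if (has_trt) {
    unknown <- setdiff(levels(d$treatment), trts)
    if (length(unknown))
      stop("unknown treatment level(s) for experiment ", experiment, ": ",
           paste(unknown, collapse = ", "))
    d$treatment <- factor(d$treatment, levels = intersect(trts, levels(d$treatment)))
  }
  fixed <- if (has_trt) "value ~ 0 + accession_id:treatment"
           else "value ~ 0 + accession_id"
  ## cell-means coding: one coefficient per GEN x TRT cell (or per GEN),
  ## so predicted means are direct and aliasing is detectable up front
  mm <- stats::model.matrix(stats::as.formula(fixed), d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("aliased fixed effects (empty or confounded cells): ",
         paste(utils::head(dropped, 5), collapse = ", "))
  }
  rterms <- experimentRandomTerms(experiment)
  ## a random term needs >= 2 observed level combinations to carry a
  ## variance component; sparser strata are dropped with a note
  nlev <- vapply(rterms, function(tm) {
    vars <- strsplit(gsub("[()|1 ]", "", tm), ":")[[1]]
    nrow(unique(d[vars]))
  }, numeric(1))
  if (any(nlev < 2))
    message("dropping single-level random term(s): ",
            paste(rterms[nlev < 2], collapse = ", "))
  rterms <- rterms[nlev >= 2]
  if (!length(rterms))
    stop("no random term has >= 2 levels; the design is degenerate")
  form <- stats::as.formula(paste(fixed, "+",
                                  paste(rterms, collapse = " + ")))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore",
                      calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual",
                                             "residual", vc$grp))
  fe <- lme4::fixef(fit)
  se <- tryCatch(stats::coef(summary(fit))[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(fe)),
                 warning = function(w) rep(NA_real_, length(fe)))
  structure(list(fit = fit, experiment = experiment,
                 fixed = data.frame(term = names(fe),
                                    estimate = unname(fe),
                                    se = unname(se),
                                    row.names = NULL),
                 varcomp = varcomp,
                 reml_loglik = as.numeric(stats::logLik(fit)),
                 has_treatment = has_trt,
                 data = d),
            class = "stresshap_lmm")
}

#' Genotypic predicted means from a bioassay fit
#'
#' Fixed-effect-based predicted cell means per accession x treatment
#' combination (per accession for experiments 3-4), with every random
#' term set to zero.  BLUP-shrunken means (conditional modes added) are
#' available with \code{blup = TRUE}; the choice is recorded in the
#' \code{"type"} attribute.
#'
#' @param lmm result of [fitExperimentLmm()].
#' @param blup add accession-level BLUPs where an accession random term
#'   exists (none in these designs, so this currently returns the same
#'   means; kept as an explicit, recorded switch).
#' @return data.frame \code{accession_id}, (\code{treatment}),
#'   \code{mean}.
#' @export
predictedMeans <- function(lmm, blup = FALSE) {
  stopifnot(inherits(lmm, "stresshap_lmm"))
  d <- lmm$data
  if (lmm$has_treatment) {
    grid <- expand.grid(accession_id = levels(d$accession_id),
                        treatment = levels(d$treatment),
                        KEEP.OUT.ATTRS = FALSE)
    observed <- unique(d[, c("accession_id", "treatment")])
    key <- paste(grid$accession_id, grid$treatment)
    if (!all(key %in% paste(observed$accession_id, observed$treatment)))
      stop("requested cell absent from design")
  } else {
    grid <- data.frame(accession_id = levels(d$accession_id))
  }
  grid$mean <- stats::predict(lmm$fit, newdata = grid, re.form = NA)
  grid$accession_id <- as.character(grid$accession_id)
  if (lmm$has_treatment) grid$treatment <- as.character(grid$treatment)
  attr(grid, "type") <- if (blup) "blup" else "fixed"
  grid
}

#' Derive the seven per-accession stress responses
#'
#' Percentage-reduction responses from experiments 1-2:
#' \code{100 * (W_baseline - W_treatment) / W_baseline}, where the
#' baseline is the unstressed control, except Drought&Pieris whose
#' baseline is the drought-only treatment.  Thrips damage (mm2) and
#' aphid counts pass through unchanged.  Negative responses (stressed
#' plants heavier than baseline) are valid values.
#'
#' @param means_exp1,means_exp2 predicted means from experiments 1 and 2
#'   ([predictedMeans()] output with a \code{treatment} column).
#' @param means_exp3,means_exp4 predicted means from experiments 3 and 4
#'   (no treatment column).
#' @return data.frame with \code{accession_id} and columns
#'   \code{Drought}, \code{P_rapae}, \code{Drought_Pieris},
#'   \code{Botrytis_Pieris}, \code{P_xylostella}, \code{F_occidentalis},
#'   \code{M_persicae}; accessions absent from an experiment get NA for
#'   its traits.
#' @export
deriveStressResponses <- function(means_exp1, means_exp2, means_exp3,
                                  means_exp4) {
  pct <- function(means, trt, baseline) {
    w <- stats::reshape(means, idvar = "accession_id",
                        timevar = "treatment", direction = "wide")
    names(w) <- sub("^mean\\.", "", names(w))
    for (col in c(trt, baseline))
      if (!col %in% names(w))
        stop("treatment '", col, "' absent from predicted means")
    bad <- !is.na(w[[baseline]]) & w[[baseline]] <= 0
    if (any(bad))
      stop("baseline mean <= 0 for accession(s): ",
           paste(utils::head(w$accession_id[bad], 5), collapse = ", "))
    data.frame(accession_id = w$accession_id,
               response = 100 * (w[[baseline]] - w[[trt]]) / w[[baseline]])
  }
  resp <- list(
    Drought         = pct(means_exp1, "drought", "control"),
    P_rapae         = pct(means_exp1, "p_rapae", "control"),
    Drought_Pieris  = pct(means_exp1, "drought_pieris", "drought"),
    Botrytis_Pieris = pct(means_exp1, "botrytis_pieris", "control"),
    P_xylostella    = pct(means_exp2, "p_xylostella", "control"),
    F_occidentalis  = data.frame(accession_id = means_exp3$accession_id,
                                 response = means_exp3$mean),
    M_persicae      = data.frame(accession_id = means_exp4$accession_id,
                                 response = means_exp4$mean))
  ids <- sort(unique(unlist(lapply(resp, `[[`, "accession_id"))))
  out <- data.frame(accession_id = ids)
  for (nm in names(resp))
    out[[nm]] <- resp[[nm]]$response[match(ids, resp[[nm]]$accession_id)]
  out
}

#' Classify accessions as winter or summer annuals
#'
#' Winter annuals require vernalization to flower: an accession is
#' classified winter iff its flowering time without vernalization is
#' \code{>= threshold_days} (inclusive) or it never flowered (censored).
#'
#' @param flowering data.frame with \code{accession_id},
#'   \code{flowering_time_days}, optionally
#'   \code{flowering_time_after_vernalization_days} and a logical
#'   \code{censored} column for plants that never flowered.
#' @param threshold_days classification threshold (days), default 75.
#' @return the input with a \code{strategy} column (\code{"winter"} /
#'   \code{"summer"}).
#' @export
classifyLifeCycle <- function(flowering, threshold_days = 75) {
  if (!all(c("accession_id", "flowering_time_days") %in% names(flowering)))
    stop("need accession_id and flowering_time_days columns")
  cens <- if ("censored" %in% names(flowering)) flowering$censored
          else rep(FALSE, nrow(flowering))
  cens[is.na(cens)] <- FALSE
  miss <- is.na(flowering$flowering_time_days) & !cens
  if (any(miss))
    stop("missing flowering time for accession(s): ",
         paste(utils::head(flowering$accession_id[miss], 5), collapse = ", "))
  winter <- cens | (!is.na(flowering$flowering_time_days) &
                    flowering$flowering_time_days >= threshold_days)
  flowering$strategy <- ifelse(winter, "winter", "summer")
  flowering
}
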