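---
title: "Models and methods in stresshap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stresshap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stresshap` analyses stress-response variation in panels of inbred
*Arabidopsis thaliana* accessions: heritable variation in responses to
drought, chewing and piercing-sucking herbivores and fungal infection,
its relationship to the winter/summer life-cycle dichotomy and to
geography, trade-offs between responses, and a two-trait genome-wide
association scan. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation
does and does not establish.

## Data containers

Genotypes are held as a `GenotypeMatrix`: an accessions × markers
matrix of exact 0/1 calls (haploid allele-dosage coding for inbred
lines) with a `GRanges` of marker coordinates, sorted by chromosome and
position. The validity method rejects heterozygous, missing or diploid
0/1/2 calls outright: the intended substrate is a post-QC, imputed SNP
set, and silent imputation or rescaling would change every downstream
covariance. Kinship lives in a `KinshipMatrix` carrying its estimator
label and any ridge applied.

## Kinship

The default estimator is the standardized (VanRaden-type) cross-product
`K = Z Zᵀ / m` over polymorphic markers, where `Z` is the
column-centred, column-scaled call matrix; an identity-by-state
estimator (proportion of matching calls) is available. The literature
that this workflow follows does not print its kinship formula, so the
estimator is a recorded configuration field rather than an assertion —
heritabilities and MTMM components change with it. If the smallest
eigenvalue of the raw estimate falls below −10⁻⁸, a ridge
`δI, δ = |λ_min| + 10⁻⁸` is added and recorded; every downstream solver
requires positive semi-definite K. Geographic subsetting (the European
window: latitude ≥ 30°, longitude −50°…50°, elevation ≤ 2000 m) uses
inclusive bounds on all four limits.

## Population structure

PCA is computed on the same scaled matrix; explained fractions are
relative to its total variance (the number of polymorphic markers).
Spatial weights are built on raw (longitude, latitude) coordinates —
planar Euclidean distances, matching the convention of the classical
neighbour-list tools; a haversine alternative was considered and left
out because at the European window's extent the neighbour sets differ
negligibly and the planar choice matches the cited default. The default
graph is the symmetrized 5-nearest-neighbour graph; a Gabriel graph is
available, and the choice is recorded because it changes which PCs pass
the autocorrelation screen. Weights are row-standardized by default
("W"); binary ("B") weights are available since the original tooling's
default is not asserted.

Moran's I uses the double-sum definition with the analytic
randomization-variance normal approximation, or a seeded permutation
test with two-sided p = (1 + #{|I′−E[I]| ≥ |I−E[I]|})/(n_perm+1).
Spatially informative PCs are selected by a *prefix scan*: PC1 upward,
stopping at the first PC whose Moran p-value fails α = 0.001. The
phrase "first k components with highest spatial autocorrelation" could
also mean any passing PC regardless of rank, so that rule is available
behind `rule = "any"`; the scan rule and retained set are recorded in
the result. Accessions are grouped by Ward clustering (`ward.D2` on
Euclidean distances of the retained PC scores — verified against an
exhaustive minimum-ESS-increase oracle for small n) and the group count
is a required parameter with study default 10; no automatic selection
is attempted because none is documented for the original analysis.
Group effects on phenotypes are tested per trait by the type-II F test
of `response ~ life_cycle + group`.

## Bioassay models and derived responses

Each experiment's per-plant measurements are fitted by REML through
lme4, with one independent variance component per design stratum:
blocks, racks, shelves and their nested tray/x/y interactions
(experiment 1), block/tray/x/y (experiment 2), block and sub-block
within block (experiments 3–4). The fixed part is a cell-means
parameterization of genotype × treatment (genotype only for 3–4), which
makes empty or confounded cells detectable up front (an error naming
the cells) and makes "genotypic predicted means" literal: fixed-effect
cell predictions with random terms at zero. The alternative reading of
predicted values as BLUP-shrunken means is kept behind a flag and
recorded in the output's `type` attribute. Strata with fewer than two
observed levels in a given data set are dropped with a message — a
variance is not identifiable from one level.

Responses are percentage biomass reduction relative to the unstressed
control, except drought-plus-herbivory which is relative to drought
alone; negative values (stressed plants heavier than baseline) are
valid data. Thrips damage (mm²) and aphid counts pass through
unchanged. A baseline predicted mean ≤ 0 g is an error for that
accession: the ratio is undefined, and a negative baseline weight is a
data problem, not a response. Accessions are winter annuals iff
flowering time without vernalization is ≥ 75 days (inclusive) or the
plant never flowered.

## Heritability

For each response, `y = μ + g + e` with `g ~ N(0, va·K)`,
`e ~ N(0, ve·I)`. One eigendecomposition of K diagonalizes the problem;
the restricted likelihood is profiled to a 1-D search over
log(va/ve) ∈ [−10, 10]·log 10 by Brent's method. Boundary optima are
reported as exactly h² = 0 or 1 with a flag, and the component pair is
made consistent with the rounded ratio. With an identity (equal
eigenvalue) kinship the ratio is unidentified: the estimator returns a
documented degenerate h² = 0 with a warning rather than an arbitrary
interior value. Standard errors come from the numerical curvature of
the profile likelihood. The model runs on the derived per-accession
responses (genotypic means), matching the pipeline order in which
responses are derived first and then analysed; a replicate-level
variant was considered out of scope for v1. The summary table reports
Min/Mean/Max/CV%/N on each trait's own scale (percent, mm², counts).

## Bayesian animal models

Three model types share one sampler: (1) Gaussian models of each
response on life cycle, elevation, latitude and longitude (geographic
covariates untransformed, so effects are per degree / per metre);
(2) a probit threshold model for the binary life-cycle label on the
gradients; (3) trade-off models of each single stress on the other
single-stress responses plus life cycle. Fixed effects take flat
priors; variances take scaled inverse-gamma (V, ν) priors — V = 1,
ν = 0.002 for the Gaussian models, V = 0.002/2.002, ν = 2.002 on the
genetic component of the threshold model, whose residual variance is
fixed at 1 for identifiability. Default chains: 150,000 iterations,
thinning 50, burn-in 50,000; the threshold model runs all three
ten-fold longer.

The sampler is a collapsed Gibbs scheme in the kinship eigenbasis,
where the marginal covariance given the variances is diagonal,
`diag(va·λᵢ + ve)`: β is drawn from its exact GLS conditional with the
genetic effects integrated out, and (va, ve) by univariate slice
sampling of the genetic-effect-marginalized posterior, alternating an
axis-aligned sweep in (log va, log ve) with a ridge-aligned sweep in
(log va/ve, log(va+ve)). The textbook single-site alternative —
drawing the genetic effects and then conjugate inverse-gamma variances
— was implemented first and rejected: on realistic fixtures its
variance chains carried lag-1 autocorrelation of 0.3–0.7 even at
thinning 50, far above the 0.1 diagnostic this workflow requires,
because va and ve random-walk along their near-flat ridge. The
collapsed chain meets the diagnostic at the default thinning; lag-1
autocorrelation and effective sample size are reported per parameter
and a flag is raised when any exceeds 0.1. The threshold model keeps
truncated-normal latent augmentation (partially collapsed scan:
genetic effects conjugately, liability by inverse-CDF truncation, then
β and va marginally).

Summaries are posterior means, 95% highest-posterior-density intervals
(the equal-tailed variant is a flag), and
pMCMC = 2·min(P(θ>0), P(θ<0)), floored at 2/(retained draws) so it is
never zero — the statistic is conventional in this literature but
rarely defined, so it is fixed here. The genetic-variance posterior
mean is reported as the "plant genealogy" column of the model tables;
it is a variance on the trait's squared scale. pMCMC calibration under
a true null is a large-sample property: at n ≈ 60 the probit model is
visibly anti-conservative, at n ≈ 200–300 (the study's range) null
covariates pass at the nominal rate.

## MTMM association scan

The two composite phenotypes are PC1 of the standardized
summer-resistant responses (P. rapae, P. xylostella, drought+Pieris,
Botrytis+Pieris) and PC1 of the winter-resistant ones
(F. occidentalis, M. persicae, drought). PC1 sign is arbitrary, so each
composite is oriented to correlate positively with its group's mean
standardized response and then scaled to unit variance — without a
deterministic convention, every downstream effect sign would be
seed-dependent.

The stacked 2n model `y = s₁μ₁ + s₂μ₂ + xβ + (x∘s₁)α + υ` has
`cov(υ) = Vg ⊗ K + Ve ⊗ I` (trait-block ordering). Vg and Ve are
estimated once under the no-SNP null by REML over their six free
parameters in a log-Cholesky parameterization (PSD by construction),
initialized from single-trait fits, with Nelder-Mead restarts; the
model display's interaction term is read as the interaction regressor
`x∘s₁` times the coefficient α. With exactly duplicated traits the
restricted likelihood diverges along the correlation → 1 boundary, so
persistent non-convergence returns the best iterate with a warning
instead of failing. With an identity-like kinship only Vg + Ve is
identified, and the fit flags itself accordingly.

Per SNP (MAF strictly > 0.05), the estimated covariance is held fixed
— the EMMAX-style plug-in, chosen for tractability over re-estimating
components per SNP; the approximation is standard but worth naming
because the source workflow does not discuss it. After whitening with
the per-eigenvalue 2×2 Cholesky factors, three exact-F nested tests
are computed: full (β = α = 0, 2 numerator df), common (β, 1 df) and
specific (α given β, 1 df), each with denominator df = 2n − rank of
the larger design. With Ω ∝ I they reduce exactly to stacked OLS — the
oracle used in the tests.

QTL windows: SNPs with −log₁₀(p) ≥ 4 for the chosen test (default
"specific", matching the phrase "trait-specific SNPs"; configurable)
seed windows of 20 kb *total* width (±10 kb), floored at position 1;
overlapping windows merge per chromosome into numbered regions
(GRanges; BED export converts to 0-based half-open). The 20 kb phrase
is ambiguous between total and half-window; total is the default here
because the companion LD listing separately calls 20 kb a
"half window", which is the `ldR2()` default.

## The synthetic generator

`simulationTruth()` defaults are the study conditions: 308 accessions,
ten demes (so roughly ten Ward groups are recoverable), per-trait
means, heritabilities and total variances on the scale of the published
summary table, the published winter-vs-summer effect sizes with their
sign pattern (winter annuals more drought/thrips/aphid-resistant,
summer annuals more caterpillar-resistant), genetic correlations of
−0.5 for the two published trade-off pairs (drought/P. rapae and
P. rapae/M. persicae) and zero elsewhere (PSD-checked), and a
winter-annual fraction of 89/308 produced by a probit on standardized
latitude (+) and elevation (−) with a kinship-structured liability
component (liability h² = 0.3, a plausible mid-range value; not a
published quantity). The marker count defaults to 3000 — a desk-scale
stand-in for a dense SNP set; IBD structure, not marker density, is
what downstream inference is sensitive to.

Genotypes: deme allele frequencies drift on the logit scale from a
common ancestral frequency with exponentially range-correlated spatial
deviations (scale 1.5, range 12°), accessions draw Bernoulli haplotypes
from their deme, coordinates are deme locations plus jitter; markers
that come out monomorphic are dropped, so realized marker counts sit
slightly below nominal. Bioassay tables invert the percentage-reduction
definition around log-normal baseline weights (median 10 g — arbitrary
and inert, since percentages are scale-free), add block (variance 2),
positional (0.5) and residual (1) effects, and mirror the four designs,
including three check accessions repeated in every temporal block of
experiment 1 — without them, block effects are confounded with the
genotype cells (each other accession sits in one block) and the block
variance is not cleanly estimable, which is precisely why the original
design included repeated calibration accessions. Flowering times are
75 + 25·liability days, so the threshold rule reproduces the planted
labels exactly; liabilities above 3 carry a censored (never-flowered)
flag.

What passing the synthetic suite shows: the estimators recover planted
truth under the model's own assumptions (additive architecture,
Gaussian noise, Bernoulli-per-deme LD structure). What it does not
show: robustness to real-data features the generator omits —
within-chromosome LD beyond deme structure, non-Gaussian and
heteroskedastic bioassay noise, missing data patterns, genotyping
error, selection-driven covariance between geography and genotype
beyond drift.

## Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` run at sizes chosen so the
statistical claims are meaningful at desk scale: heritability recovery
and effect recovery at n = 300 accessions × 1500–2000 markers over 20
replicate seeds, MTMM calibration on ~1000 SNPs at n = 300, MCMC
checks on chains of 6,000–15,000 iterations (the package defaults
remain the full published chain lengths), exhaustive oracles at n ≤ 8.
Under the structured IBD panel a single h² estimate at n = 300 carries
a standard deviation near 0.19 — the effective dimension of a
structured kinship is far below n — which is why recovery statements
are about means over seeds. All seeded functions restore the caller's
RNG state; identical inputs and seeds give bit-identical chains and
generator output. Ties in k-NN neighbour distances break by index
order with a note; Gabriel graphs refuse coincident points; constant
trait vectors, constant SNPs, singular kinships and separated probit
covariates are all explicit, documented outcomes rather than silent
ones.

## Known limitations

Single-kinship additive models only (no epistatic or multi-kinship
components); two traits in the MTMM (not p > 2); no spatial residual
correlation (AR1×AR1) in the bioassay models; no genomic-control
correction or gene annotation downstream of the QTL windows; asymptotic
rather than bootstrap uncertainty for h²; the heritability model uses
genotypic means, not replicate-level data.
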