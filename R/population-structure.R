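## Population structure: PCA of the scaled marker matrix, spatial
## neighbour weights, Moran's I, selection of spatially informative PCs,
## Ward clustering into genetic groups, and the group-effect ANOVA.

#' PCA of the scaled marker matrix
#'
#' Principal component analysis of the column-centred, column-scaled
#' 0/1 call matrix (monomorphic markers dropped).  Explained fractions
#' are relative to the total variance of the scaled matrix (= number of
#' polymorphic markers).
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param n_components number of PCs to return
#'   (<= min(n - 1, m)).
#' @return list with \code{scores} (n x p, rownames = accession ids),
#'   \code{explained_fraction}, \code{loadings}, class
#'   \code{"stresshap_pca"}.
#' @export
pcaMarkers <- function(geno, n_components = 10) {
  stopifnot(is(geno, "GenotypeMatrix"))
  X <- callMatrix(geno)
  poly <- minorAlleleFrequency(geno) > 0
  if (sum(poly) < 1) stop("all markers monomorphic; PCA undefined")
  Z <- scale(X[, poly, drop = FALSE])
  n <- nrow(Z)
  if (n_components > min(n - 1, ncol(Z)))
    stop("n_components exceeds min(n - 1, m)")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  total_var <- ncol(Z)                    # each scaled column has variance 1
  keep <- seq_len(n_components)
  structure(list(
    scores = pc$x[, keep, drop = FALSE],
    explained_fraction = pc$sdev[keep]^2 / total_var,
    loadings = pc$rotation[, keep, drop = FALSE]
  ), class = "stresshap_pca")
}

#' Spatial neighbour weights over accession collection sites
#'
#' Builds a neighbour graph on the raw (longitude, latitude) plane --
#' matching the planar default of the classical neighbour-list tools --
#' symmetrizes it by union, and row-standardizes the weights.
#'
#' @param geo data.frame with \code{accession_id}, \code{latitude},
#'   \code{longitude} (one row per accession, >= 2 distinct points).
#' @param scheme \code{"knn"} (symmetrized k-nearest-neighbour, default
#'   k = 5) or \code{"gabriel"} (Gabriel graph: i-j are neighbours iff
#'   no third point falls inside the circle with diameter ij).
#' @param k neighbours per point for \code{"knn"}; distance ties broken
#'   by index order (noted via message).
#' @param style \code{"W"} row-standardized (default) or \code{"B"}
#'   binary weights.
#' @return list with \code{ids}, \code{neighbours} (list of integer
#'   vectors), \code{weights} (matching list), \code{W} (dense n x n
#'   weight matrix), \code{scheme}; class \code{"stresshap_listw"}.
#' @export
buildSpatialWeights <- function(geo, scheme = c("knn", "gabriel"), k = 5,
                                style = c("W", "B")) {
  scheme <- match.arg(scheme)
  style <- match.arg(style)
  pts <- cbind(geo$longitude, geo$latitude)
  n <- nrow(pts)
  if (n < 2) stop("need >= 2 points")
  if (nrow(unique(pts)) < 2) stop("need >= 2 distinct coordinates")
  D <- as.matrix(stats::dist(pts))
  A <- matrix(FALSE, n, n)
  if (scheme == "knn") {
    if (k >= n) stop("k must be < number of points")
    for (i in seq_len(n)) {
      d <- D[i, ]; d[i] <- Inf
      o <- order(d)                       # ties broken by index order
      if (any(duplicated(d[o[seq_len(min(k + 1, n - 1))]])))
        message("knn distance ties broken by index order")
      A[i, o[seq_len(k)]] <- TRUE
    }
    A <- A | t(A)                         # symmetrize by union
  } else {
    if (nrow(unique(pts)) < n)
      stop("coincident points not supported by the gabriel scheme")
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      mid <- (pts[i, ] + pts[j, ]) / 2
      r2 <- sum((pts[i, ] - pts[j, ])^2) / 4
      others <- setdiff(seq_len(n), c(i, j))
      d2 <- colSums((t(pts[others, , drop = FALSE]) - mid)^2)
      if (all(d2 > r2 + 1e-12)) A[i, j] <- A[j, i] <- TRUE
    }
  }
  W <- matrix(0, n, n)
  W[A] <- 1
  if (style == "W") {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  nb <- lapply(seq_len(n), function(i) which(A[i, ]))
  ids <- if (!is.null(geo$accession_id)) as.character(geo$accession_id)
         else as.character(seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(list(ids = ids, neighbours = nb,
                 weights = lapply(seq_len(n), function(i) W[i, nb[[i]]]),
                 W = W, scheme = scheme, style = style),
            class = "stresshap_listw")
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = (n / S_0) \sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x) /
#'   \sum_i (x_i - \bar x)^2.}
#' The analytic p-value uses the normal approximation with the
#' randomization variance; the permutation p-value relabels values
#' across sites with a fixed seed and is two-sided around
#' \eqn{E[I] = -1/(n-1)}.
#'
#' @param values numeric vector over accessions (length n, non-constant).
#' @param w weights from [buildSpatialWeights()].
#' @param method \code{"analytic"} or \code{"permutation"}.
#' @param n_perm permutations (permutation method).
#' @param seed RNG seed for the permutation method.
#' @return list with \code{statistic}, \code{expectation}, \code{sd}
#'   (analytic), \code{p_value}, \code{method}; class
#'   \code{"stresshap_moran"}.
#' @export
moransI <- function(values, w, method = c("analytic", "permutation"),
                    n_perm = 999, seed = 1) {
  method <- match.arg(method)
  W <- w$W
  n <- nrow(W)
  if (length(values) != n) stop("values length must match weights")
  if (stats::var(values) == 0) stop("Moran's I undefined for constant values")
  I_obs <- moranStat(values, W)
  E_I <- -1 / (n - 1)
  if (method == "analytic") {
    z <- values - mean(values)
    S0 <- sum(W)
    S1 <- sum((W + t(W))^2) / 2
    S2 <- sum((rowSums(W) + colSums(W))^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - E_I^2
    sdI <- sqrt(varI)
    p <- 2 * stats::pnorm(abs((I_obs - E_I) / sdI), lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
    out <- list(statistic = I_obs, expectation = E_I, sd = sdI,
                p_value = p, method = method)
  } else {
    I_perm <- withSeed(seed,
      replicate(n_perm, moranStat(sample(values), W)))
    p <- (1 + sum(abs(I_perm - E_I) >= abs(I_obs - E_I))) / (n_perm + 1)
    out <- list(statistic = I_obs, expectation = E_I, sd = stats::sd(I_perm),
                p_value = p, method = method, n_perm = n_perm, seed = seed)
  }
  structure(out, class = "stresshap_moran")
}

moranStat <- function(x, W) {
  z <- x - mean(x)
  n <- length(x)
  (n / sum(W)) * as.numeric(z %*% W %*% z) / sum(z^2)
}

#' Select spatially informative principal components
#'
#' Scans PCs from PC1 upward, testing each for spatial autocorrelation
#' by Moran's I, and retains the leading consecutive run whose p-values
#' fall below \code{alpha} (default 0.001), stopping at the first
#' failure.  The alternative rule \code{rule = "any"} retains every PC
#' passing regardless of position.
#'
#' @param pca result of [pcaMarkers()].
#' @param w weights from [buildSpatialWeights()].
#' @param alpha significance cutoff on the Moran p-value.
#' @param rule \code{"prefix"} (default) or \code{"any"}.
#' @param method,n_perm,seed passed to [moransI()].
#' @return list with \code{retained} (integer PC indices),
#'   \code{p_values}, \code{statistics}, \code{rule}, \code{alpha},
#'   \code{explained_fraction} (summed over retained PCs).
#' @export
selectInformativePcs <- function(pca, w, alpha = 0.001,
                                 rule = c("prefix", "any"),
                                 method = "analytic", n_perm = 999,
                                 seed = 1) {
  rule <- match.arg(rule)
  p <- ncol(pca$scores)
  mor <- lapply(seq_len(p), function(j)
    moransI(pca$scores[, j], w, method = method, n_perm = n_perm,
            seed = seed + j))
  pv <- vapply(mor, `[[`, numeric(1), "p_value")
  stat <- vapply(mor, `[[`, numeric(1), "statistic")
  pass <- pv < alpha
  retained <- if (rule == "prefix") {
    r <- 0
    while (r < p && pass[r + 1]) r <- r + 1
    seq_len(r)
  } else which(pass)
  list(retained = retained, p_values = pv, statistics = stat,
       rule = rule, alpha = alpha,
       explained_fraction = sum(pca$explained_fraction[retained]))
}

#' Ward clustering of accessions into genetic groups
#'
#' Agglomerative clustering of the retained PC scores under the Ward
#' minimum-increase-of-within-cluster-sum-of-squares criterion on
#' Euclidean distances, cut into \code{n_groups} groups.
#'
#' @param scores n x k numeric matrix (rownames = accession ids).
#' @param n_groups number of groups in [1, n].
#' @return list with \code{k}, \code{assignment} (named integer vector,
#'   labels 1..k, contiguous), \code{merge} (hclust merge matrix),
#'   \code{height}, \code{hclust}; class \code{"stresshap_groups"}.
#' @export
wardCluster <- function(scores, n_groups) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n_groups < 1 || n_groups > n) stop("n_groups must be in [1, n]")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  raw <- stats::cutree(hc, k = n_groups)
  ## relabel contiguously in order of first appearance
  lab <- as.integer(factor(raw, levels = unique(raw)))
  names(lab) <- rownames(scores)
  structure(list(k = n_groups, assignment = lab, merge = hc$merge,
                 height = hc$height, hclust = hc),
            class = "stresshap_groups")
}

#' Per-trait ANOVA for the genetic-group effect after life-cycle correction
#'
#' Fits \code{response ~ life_cycle + group} by least squares per trait
#' and reports the type-II F test for the group factor.
#'
#' @param responses data.frame with \code{accession_id} plus one column
#'   per trait.
#' @param groups result of [wardCluster()] (every accession assigned).
#' @param life_cycle named vector (or factor) of \code{"winter"} /
#'   \code{"summer"} labels per accession.
#' @return data.frame with \code{trait}, \code{F}, \code{df1},
#'   \code{df2}, \code{p_value}.
#' @export
clusterPhenotypeAnova <- function(responses, groups, life_cycle) {
  ids <- responses$accession_id
  g <- groups$assignment[ids]
  lc <- life_cycle[ids]
  if (anyNA(g) || anyNA(lc))
    stop("every accession needs a group and a life-cycle label")
  if (any(table(g) < 2))
    stop("some group has < 2 accessions; reduce n_groups")
  traits <- setdiff(names(responses), "accession_id")
  res <- lapply(traits, function(tr) {
    d <- data.frame(y = responses[[tr]], lc = factor(lc),
                    grp = factor(g))
    fit <- stats::lm(y ~ lc + grp, data = d)
    a <- car::Anova(fit, type = 2)
    i <- match("grp", rownames(a))
    data.frame(trait = tr, F = a$`F value`[i], df1 = a$Df[i],
               df2 = a$Df[nrow(a)], p_value = a$`Pr(>F)`[i])
  })
  do.call(rbind, res)
}
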