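# Deterministic fixtures built in code.

# tiny genotype matrix with known calls; 4 accessions x 6 markers on
# two chromosomes
toyGenotypes <- function() {
  calls <- rbind(
    a1 = c(0, 1, 0, 1, 0, 0),
    a2 = c(1, 1, 0, 0, 0, 1),
    a3 = c(0, 0, 1, 1, 0, 1),
    a4 = c(1, 0, 1, 0, 0, 1))
  colnames(calls) <- paste0("s", 1:6)
  GenotypeMatrix(calls, chromosome = rep(c("1", "2"), each = 3),
                 position = c(100L, 200L, 300L, 150L, 250L, 350L))
}

randomGenotypes <- function(n, m, seed, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  calls <- matrix(rbinom(n * m, 1, rep(p, each = n)), n, m,
                  dimnames = list(sprintf("acc%03d", seq_len(n)), NULL))
  GenotypeMatrix(calls, chromosome = rep("1", m),
                 position = seq_len(m) * 100L)
}

# small geographic table on a grid
gridGeo <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(accession_id = sprintf("acc%03d", seq_len(n)),
             latitude = runif(n, 35, 60),
             longitude = runif(n, -10, 40),
             elevation = runif(n, 0, 1500))
}

# exhaustive O(n^3) Ward oracle: greedy merges minimizing the increase
# in within-cluster sum of squares; returns the list of partitions
# (cluster membership vectors) after each merge
wardOracle <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  ess_seq <- numeric()
  ess <- function(members) {
    Y <- X[members, , drop = FALSE]
    sum(scale(Y, scale = FALSE)^2)
  }
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      delta <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (delta < best[1]) best <- c(delta, i, j)
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    memb <- integer(n)
    for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- memb
    ess_seq <- c(ess_seq, sum(vapply(clusters, ess, numeric(1))))
  }
  list(partitions = partitions, ess = ess_seq)
}

# canonical form of a partition for label-free comparison
canonicalPartition <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

# brute-force stacked-OLS nested-model F tests for one SNP under
# identity covariance (the MTMM oracle)
stackedOlsF <- function(p1, p2, x) {
  n <- length(p1)
  y <- c(p1, p2)
  s1 <- rep(c(1, 0), each = n)
  s2 <- rep(c(0, 1), each = n)
  xx <- c(x, x)
  xs <- c(x, rep(0, n))
  rss <- function(M) sum(lm.fit(M, y)$residuals^2)
  r0 <- rss(cbind(s1, s2))
  rc <- rss(cbind(s1, s2, xx))
  rf <- rss(cbind(s1, s2, xx, xs))
  df_f <- 2 * n - 4
  df_c <- 2 * n - 3
  list(
    F_full = ((r0 - rf) / 2) / (rf / df_f),
    F_common = ((r0 - rc) / 1) / (rc / df_c),
    F_specific = ((rc - rf) / 1) / (rf / df_f),
    p_full = pf(((r0 - rf) / 2) / (rf / df_f), 2, df_f, lower.tail = FALSE),
    p_common = pf(((r0 - rc) / 1) / (rc / df_c), 1, df_c, lower.tail = FALSE),
    p_specific = pf(((rc - rf) / 1) / (rf / df_f), 1, df_f,
                    lower.tail = FALSE))
}

# brute-force double-sum Moran's I
moranOracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# small simulated panel shared across tests (cached per session)
smallPanel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- simulationTruth(n_accessions = 60, n_markers = 600,
                               seed = 11)
      sim <- simulateGenotypesIbd(truth)
      ph <- simulatePhenotypes(sim$geno, sim$geo, truth)
      cache <<- list(truth = truth, geno = sim$geno, geo = sim$geo,
                     ph = ph, K = ph$K)
    }
    cache
  }
})

# crude effective sample size for Monte-Carlo error bars in tests
effectiveSizeForTest <- function(x) {
  ac <- acf(x, lag.max = min(length(x) - 1, 100), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  length(x) / (1 + 2 * s)
}
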