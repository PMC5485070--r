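## Small internal helpers.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
## state afterwards so that seeded package functions do not perturb the
## user's random stream.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Shortest interval containing `prob` of the sampled mass (empirical
## highest-posterior-density interval, the convention of the animal-model
## summaries).
hpdInterval <- function(samples, prob = 0.95) {
  x <- sort(samples)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + m])
}

## Two-sided Bayesian significance: 2 * min(P(theta > 0), P(theta < 0)),
## floored at 2 / n so it is never reported as exactly zero.
pmcmcStat <- function(samples) {
  n <- length(samples)
  max(2 * min(mean(samples > 0), mean(samples < 0)), 2 / n)
}

## Lag-1 autocorrelation of a chain.
lag1Autocorrelation <- function(x) {
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(NA_real_)
  stats::cor(x[-1], x[-n])
}

## Effective sample size via initial positive sequence of autocorrelations.
effectiveSize <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}
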