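# Shared fixtures and small numeric helpers for the suite. Everything is
# generated in code under fixed seeds.

# batch-means standard error for (possibly autocorrelated) MCMC draws
batchSE <- function(x, nBatch = 20) {
  n <- length(x)
  b <- floor(n / nBatch)
  means <- vapply(seq_len(nBatch), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  sd(means) / sqrt(nBatch)
}

# small genotype/phenotype pair with known truth
tinyData <- function(n = 100, p = 30, nQtl = 3, h2 = 0.6, gseed = 1,
                     pseed = 2, maf = c(0.1, 0.5)) {
  Z <- simulateGenotypes(n, p, maf, seed = gseed)
  sim <- simulatePhenotypes(Z, nQtl, h2, seed = pseed)
  list(Z = Z, y = sim$y, truth = sim$truth)
}

# over-dispersed AR(1) chains converging to a common stationary law
arChains <- function(m = 4, n = 2000, phi = 0.95, seed = 1) {
  withStream(seed, 0L, {
    starts <- seq(-10, 10, length.out = m)
    lapply(seq_len(m), function(i) {
      x <- numeric(n)
      x[1] <- starts[i]
      for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1) * sqrt(1 - phi^2)
      matrix(x, ncol = 1, dimnames = list(NULL, "x"))
    })
  })
}

# exact joint normal posterior of (mu, beta) for fixed-variance regression
# y = 1*mu + X*beta + e, e ~ N(0, s2e), beta_j ~ N(0, s2b): the stationary
# law of the corresponding Gibbs samplers (independent linear-algebra path)
ridgeOracle <- function(X, y, s2e, s2b) {
  W <- cbind(1, X)
  D <- diag(c(0, rep(s2e / s2b, ncol(X))))
  A <- crossprod(W) + D
  mean <- solve(A, crossprod(W, y))
  list(mean = as.numeric(mean), cov = s2e * solve(A))
}
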