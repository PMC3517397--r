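## Seeded synthetic-data generators. All generators are pure functions of
## (parameters, seed): they draw from a dedicated RNG stream and restore
## the caller's RNG state.

#' Simulate genotypes in Hardy-Weinberg proportions
#'
#' Per-SNP allele frequencies are drawn uniformly from `mafRange` and
#' genotype codes as `Binomial(2, freq)` independently per individual and
#' SNP (Hardy-Weinberg equilibrium, linkage equilibrium). An optional
#' first-order autoregressive mode induces correlation between adjacent
#' SNPs as a stress-test extension.
#'
#' @param n Number of individuals.
#' @param p Number of SNPs (0 gives an empty matrix).
#' @param mafRange Numeric `(lo, hi)` with `0 < lo <= hi <= 0.5`.
#' @param seed Integer seed.
#' @param ldRho AR(1) correlation between latent allele draws of adjacent
#'   SNPs; 0 (default) = linkage equilibrium.
#' @return A [GenotypeMatrix-class].
#' @examples
#' simulateGenotypes(10, 5, c(0.1, 0.5), seed = 1)
#' @export
simulateGenotypes <- function(n, p, mafRange = c(0.05, 0.5), seed,
                              ldRho = 0) {
  stopifnot(n >= 0, p >= 0, length(mafRange) == 2)
  lo <- mafRange[1]; hi <- mafRange[2]
  if (!(lo > 0 && lo <= hi && hi <= 0.5))
    stop("invalid MAF range: need 0 < lo <= hi <= 0.5")
  stopifnot(ldRho >= 0, ldRho < 1)
  withStream(seed, 0L, {
    freq <- runif(p, lo, hi)
    if (p == 0 || n == 0) {
      g <- matrix(numeric(0), n, p)
    } else if (ldRho == 0) {
      g <- matrix(rbinom(n * p, 2L, rep(freq, each = n)), n, p)
    } else {
      ## latent Gaussian AR(1) across SNPs, thresholded at the allele
      ## frequency; two haplotypes per individual
      g <- matrix(0, n, p)
      for (h in 1:2) {
        z <- matrix(rnorm(n * p), n, p)
        for (j in 2:p) z[, j] <- ldRho * z[, j - 1] +
            sqrt(1 - ldRho^2) * z[, j]
        g <- g + (z < qnorm(rep(freq, each = n)))
      }
    }
    storage.mode(g) <- "double"
    dimnames(g) <- list(if (n) paste0("ind", seq_len(n)),
                        if (p) paste0("snp", seq_len(p)))
    new("GenotypeMatrix", geno = g)
  })
}

#' Simulate phenotypes with a known genetic architecture
#'
#' Samples `nQtl` causal SNPs without replacement, draws their effects,
#' forms genetic values `g = Z_qtl %*% effects`, and adds residuals scaled
#' so that the realized heritability `var(g) / (var(g) + var(e))` equals
#' `h2` exactly on the simulated sample.
#'
#' @param Z A [GenotypeMatrix-class].
#' @param nQtl Number of causal SNPs, `<= nSnp(Z)` (0 gives pure noise
#'   with `var(e) = 1`).
#' @param h2 Target heritability in (0, 1).
#' @param effectDist `"normal"` or `"laplace"` effect distribution.
#' @param seed Integer seed.
#' @return List with `y` (phenotypes) and `truth` (a [SimTruth-class]).
#' @export
simulatePhenotypes <- function(Z, nQtl, h2, effectDist = c("normal",
                               "laplace"), seed) {
  stopifnot(is(Z, "GenotypeMatrix"), nQtl >= 0, nQtl <= nSnp(Z),
            h2 > 0, h2 < 1)
  effectDist <- match.arg(effectDist)
  n <- nInd(Z)
  if (n < 2) stop("at least two individuals are required")
  withStream(seed, 0L, {
    if (nQtl == 0) {
      e <- rnorm(n)
      e <- e / sd(e)
      return(list(y = e,
                  truth = new("SimTruth", qtlIndices = integer(0),
                              qtlEffects = numeric(0), tbv = rep(0, n),
                              realizedH2 = 0)))
    }
    qtl <- sort(sample.int(nSnp(Z), nQtl))
    eff <- switch(effectDist,
                  normal = rnorm(nQtl),
                  laplace = rexp(nQtl) * sample(c(-1, 1), nQtl,
                                                replace = TRUE))
    g <- as.numeric(genotypes(Z)[, qtl, drop = FALSE] %*% eff)
    vg <- var(g)
    if (vg == 0)
      stop("genetic values are constant (monomorphic QTL draw); ",
           "resample with another seed or wider MAF range")
    sigmaE2 <- vg * (1 - h2) / h2
    e <- rnorm(n)
    e <- e * sqrt(sigmaE2 / var(e)) # calibrate realized residual variance
    y <- g + e
    list(y = y,
         truth = new("SimTruth", qtlIndices = as.integer(qtl),
                     qtlEffects = eff, tbv = g,
                     realizedH2 = vg / (vg + var(e))))
  })
}

#' Simulate a univariate normal fixture
#'
#' IID normal draws standing in for a large single-trait dataset; the
#' defaults mirror a body-weight daily-gain setting (n = 7670 records,
#' mean 3.394, variance 0.58).
#'
#' @param n Number of records.
#' @param mu Mean.
#' @param sigma2 Variance, > 0.
#' @param seed Integer seed.
#' @return Numeric vector of draws.
#' @export
simulateNormalFixture <- function(n = 7670L, mu = 3.394, sigma2 = 0.58,
                                  seed) {
  stopifnot(n >= 1, sigma2 > 0)
  withStream(seed, 0L, rnorm(n, mu, sqrt(sigma2)))
}

#' Simulate grouped observations for the within-chain parallel demo
#'
#' Group means `theta_i ~ N(0, sigmaTheta2)` and observations
#' `y_ij ~ N(theta_i, sigmaE2)`: the model in which location blocks are
#' conditionally independent given the scale, by construction.
#'
#' @param q Number of groups, >= 1.
#' @param nPerGroup Observations per group.
#' @param sigmaTheta2 Variance of the group means.
#' @param sigmaE2 Residual variance.
#' @param seed Integer seed.
#' @return List with `y`, `group` (integer labels), and `theta` (true
#'   group means).
#' @export
simulateGroupMeans <- function(q, nPerGroup, sigmaTheta2, sigmaE2, seed) {
  stopifnot(q >= 1, nPerGroup >= 1, sigmaTheta2 > 0, sigmaE2 > 0)
  withStream(seed, 0L, {
    theta <- rnorm(q, 0, sqrt(sigmaTheta2))
    group <- rep(seq_len(q), each = nPerGroup)
    y <- rnorm(q * nPerGroup, theta[group], sqrt(sigmaE2))
    list(y = y, group = group, theta = theta)
  })
}
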