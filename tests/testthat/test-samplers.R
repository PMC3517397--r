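# Gibbs samplers: code-path identities, conjugate oracles, prior recovery.

test_that("fixed-pi BayesC is the BayesC-pi code path draw for draw", {
  d <- tinyData(n = 60, p = 10)
  a <- bayesCFixedPiGibbs(d$Z, d$y, iters = 200, burnin = 50, seed = 4,
                          pi = 0)
  b <- bayesCPiGibbs(d$Z, d$y, hyper = bayesCHyper(piFixed = 0),
                     iters = 200, burnin = 50, seed = 4)
  expect_identical(chainDraws(a), chainDraws(b))
  expect_true(all(pip(a) == 1)) # every marker stays in the model
})

test_that("pi = 1 collapses to the mean-only model and its conjugate marginals", {
  d <- tinyData(n = 200, p = 8, gseed = 31, pseed = 32)
  # vague residual prior (nu_e = 0) makes the collapsed model exactly the
  # unknown-mean/unknown-variance normal model
  hyper <- bayesCHyper(S2Alpha = 1, nuE = 0, S2E = 1, piFixed = 1)
  fit <- bayesCPiGibbs(d$Z, d$y, hyper, iters = 6000, burnin = 1000,
                       seed = 6)
  pooled <- poolChains(fit@chains)
  expect_true(all(pooled[, paste0("delta_", snpIds(d$Z))] == 0))
  expect_true(all(pooled[, paste0("alpha_", snpIds(d$Z))] == 0))
  expect_true(all(pip(fit) == 0))

  oracle <- twoParamMarginals(d$y)
  mu <- pooled[, "mu"]
  s2e <- pooled[, "sigma2_e"]
  expect_lt(abs(mean(mu) - posteriorMean(oracle$mu)), 4 * batchSE(mu))
  expect_lt(abs(mean(s2e) - posteriorMean(oracle$sigma2)),
            4 * batchSE(s2e))
})

test_that("a single strong marker matches its conjugate posterior", {
  Z <- simulateGenotypes(50, 1, c(0.3, 0.5), seed = 41)
  z <- genotypes(Z)[, 1]
  y <- withStream(42, 0, 2.5 * z + rnorm(50, 0, 0.5))
  s2e <- 0.25
  s2a <- 10
  hyper <- bayesCHyper(S2Alpha = 1, S2E = 1, fixSigma2Alpha = s2a,
                       fixSigma2E = s2e)
  fit <- bayesCPiGibbs(Z, y, hyper, iters = 8000, burnin = 1000, seed = 43)
  pooled <- poolChains(fit@chains)
  expect_gt(pip(fit)[1], 0.99) # effect is unmissable
  oracle <- ridgeOracle(genotypes(Z), y, s2e, s2a)
  a <- pooled[, "alpha_snp1"]
  expect_lt(abs(mean(a) - oracle$mean[2]), 4 * batchSE(a))
})

test_that("fixed-variance BayesC(pi = 0) matches the ridge closed form", {
  d <- tinyData(n = 30, p = 5, nQtl = 2, gseed = 51, pseed = 52)
  s2e <- 0.5
  s2a <- 50 # effectively unshrunk
  hyper <- bayesCHyper(S2Alpha = 1, S2E = 1, fixSigma2Alpha = s2a,
                       fixSigma2E = s2e, piFixed = 0)
  fit <- bayesCPiGibbs(d$Z, d$y, hyper, iters = 10000, burnin = 2000,
                       seed = 53)
  pooled <- poolChains(fit@chains)
  oracle <- ridgeOracle(genotypes(d$Z), d$y, s2e, s2a)
  est <- c(mean(pooled[, "mu"]),
           colMeans(pooled[, paste0("alpha_", snpIds(d$Z))]))
  for (j in seq_along(est)) {
    se <- batchSE(if (j == 1) pooled[, "mu"]
                  else pooled[, paste0("alpha_", snpIds(d$Z))[j - 1]])
    expect_lt(abs(est[j] - oracle$mean[j]), 5 * se)
  }
})

test_that("orthogonal markers factorize into univariate conjugate posteriors", {
  # two exactly orthogonal (after centering) covariate columns
  g <- cbind(rep(c(0, 2), each = 16), rep(c(0, 2), times = 16))
  colnames(g) <- c("snpA", "snpB")
  Z <- GenotypeMatrix(g)
  y <- withStream(61, 0, 1.5 * (g[, 1] - 1) - 0.8 * (g[, 2] - 1) +
                    rnorm(32, 0, 0.4))
  s2e <- 0.16
  s2a <- 25
  hyper <- bayesCHyper(S2Alpha = 1, S2E = 1, fixSigma2Alpha = s2a,
                       fixSigma2E = s2e, piFixed = 0)
  fit <- bayesCPiGibbs(Z, y, hyper, iters = 8000, burnin = 1000, seed = 62,
                       center = TRUE, fixMu = TRUE)
  pooled <- poolChains(fit@chains)
  zc <- sweep(g, 2, colMeans(g))
  for (j in 1:2) {
    cj <- sum(zc[, j]^2)
    Cj <- cj + s2e / s2a
    oracle <- sum(zc[, j] * y) / Cj # univariate conjugate mean
    a <- pooled[, paste0("alpha_", colnames(g)[j])]
    expect_lt(abs(mean(a) - oracle), 4 * batchSE(a))
  }
})

test_that("with no data the sampler draws from its priors", {
  p <- 5
  Z <- GenotypeMatrix(matrix(numeric(0), 0, p,
                             dimnames = list(NULL, paste0("s", 1:p))))
  hyper <- bayesCHyper(nuAlpha = 10, S2Alpha = 2, nuE = 10, S2E = 3)
  fit <- bayesCPiGibbs(Z, numeric(0), hyper, iters = 40000, burnin = 2000,
                       thin = 4, seed = 71)
  pooled <- poolChains(fit@chains)
  s2a <- pooled[, "sigma2_alpha"]
  s2e <- pooled[, "sigma2_e"]
  piDraws <- pooled[, "pi"]
  # scaled-inv-chi2 prior moments
  expect_lt(abs(mean(s2a) - 10 * 2 / 8), 4 * batchSE(s2a))
  expect_lt(abs(mean(s2e) - 10 * 3 / 8), 4 * batchSE(s2e))
  # pi is uniform; thin further to de-correlate before the KS test
  expect_gt(ks.test(piDraws[seq(1, length(piDraws), by = 10)],
                    "punif")$p.value, 0.01)
  expect_lt(abs(mean(piDraws) - 0.5), 4 * batchSE(piDraws))
})

test_that("prior-predictive round trip keeps parameter means at prior values", {
  # successive-conditional simulation: alternate one Gibbs sweep with a
  # fresh draw of the data given the state; the marginal law of the
  # parameters must stay at the prior (intercept held at 0 so that all
  # priors are proper)
  n <- 15
  p <- 5
  Z <- simulateGenotypes(n, p, c(0.2, 0.5), seed = 81)
  Zm <- genotypes(Z)
  csum <- colSums(Zm^2)
  nuA <- 10; SA <- 0.5; nuE <- 10; SE <- 1
  M <- 30000
  out <- matrix(NA_real_, M, 3, dimnames = list(NULL, c("pi", "s2a", "s2e")))
  withStream(82, 0, {
    state <- list(mu = 0, alpha = numeric(p), delta = integer(p),
                  pi = runif(1), s2a = nuA * SA / rchisq(1, nuA),
                  s2e = nuE * SE / rchisq(1, nuE))
    y <- rnorm(n, 0, sqrt(state$s2e))
    e <- y
    for (t in seq_len(M)) {
      st <- parMCMCgp:::.bayesc_sweep(Zm, e, state$mu, state$alpha,
                                      state$delta, state$pi, state$s2a,
                                      state$s2e, csum, nuA, SA, nuE, SE,
                                      TRUE, TRUE, FALSE, FALSE)
      state <- list(mu = st$mu, alpha = st$alpha, delta = st$delta,
                    pi = st$pi, s2a = st$s2a, s2e = st$s2e)
      y <- as.numeric(Zm %*% state$alpha) +
        rnorm(n, 0, sqrt(state$s2e))
      e <- y - as.numeric(Zm %*% state$alpha)
      out[t, ] <- c(state$pi, state$s2a, state$s2e)
    }
  })
  expect_lt(abs(mean(out[, "pi"]) - 0.5), 5 * batchSE(out[, "pi"]))
  expect_lt(abs(mean(out[, "s2a"]) - nuA * SA / (nuA - 2)),
            5 * batchSE(out[, "s2a"]))
  expect_lt(abs(mean(out[, "s2e"]) - nuE * SE / (nuE - 2)),
            5 * batchSE(out[, "s2e"]))
})

test_that("the PIP of a causal marker does not decrease with its effect size", {
  Z <- simulateGenotypes(100, 20, c(0.2, 0.5), seed = 91)
  z <- genotypes(Z)[, 5]
  noise <- withStream(92, 0, rnorm(100, 0, 1))
  pips <- vapply(c(0.3, 0.6, 1.2), function(effect) {
    y <- effect * z + noise
    fit <- bayesCPiGibbs(Z, y, iters = 3000, burnin = 500, seed = 93)
    pip(fit)[["snp5"]]
  }, numeric(1))
  expect_true(all(diff(pips) >= 0))
})

test_that("GEBV prediction is the posterior-mean linear predictor", {
  d <- tinyData(n = 120, p = 40, nQtl = 5, h2 = 0.7, gseed = 101,
                pseed = 102)
  train <- 1:80
  test <- 81:120
  fit <- bayesCPiGibbs(d$Z[train, ], d$y[train], iters = 2000,
                       burnin = 500, seed = 103)
  fitted <- predictGEBV(fit, d$Z[train, ])
  pooled <- poolChains(fit@chains)
  aHat <- colMeans(pooled[, paste0("alpha_", snpIds(d$Z))])
  manual <- mean(pooled[, "mu"]) +
    as.numeric(genotypes(d$Z[train, ]) %*% aHat)
  expect_equal(fitted, manual)

  # out-of-sample predictions correlate with the true breeding values
  pred <- predictGEBV(fit, d$Z[test, ])
  expect_gt(cor(pred, d$truth@tbv[test]), 0)

  # all-null model predicts a constant
  nullFit <- bayesCPiGibbs(d$Z[train, ], d$y[train],
                           bayesCHyper(S2Alpha = 1, S2E = 1, piFixed = 1),
                           iters = 500, burnin = 100, seed = 104)
  expect_equal(var(predictGEBV(nullFit, d$Z[test, ])), 0)

  # SNP mismatch is refused
  expect_error(predictGEBV(fit, d$Z[test, 1:10]), "SNP set")
})

test_that("Bayesian LASSO matches the ridge oracle when tau2 is fixed", {
  d <- tinyData(n = 30, p = 5, nQtl = 2, gseed = 111, pseed = 112)
  tau2 <- 2
  s2e <- 1
  hyper <- lassoHyper(fixTau2 = tau2, fixSigma2E = s2e)
  fit <- bayesianLassoGibbs(d$Z, d$y, hyper, iters = 8000, burnin = 1000,
                            seed = 113)
  pooled <- poolChains(fit)
  # beta_j ~ N(0, tau2 * s2e) is a ridge prior with variance tau2 * s2e
  oracle <- ridgeOracle(genotypes(d$Z), d$y, s2e, tau2 * s2e)
  bhat <- colMeans(pooled[, paste0("beta_", snpIds(d$Z))])
  for (j in 1:5) {
    se <- batchSE(pooled[, paste0("beta_", snpIds(d$Z))[j]])
    expect_lt(abs(bhat[j] - oracle$mean[j + 1]), 5 * se)
  }
})

test_that("a huge regularization parameter shrinks all effects to zero", {
  d <- tinyData(n = 50, p = 10, nQtl = 3, gseed = 121, pseed = 122)
  y <- as.numeric(scale(d$y))
  fit <- bayesianLassoGibbs(d$Z, y, lassoHyper(fixLambda2 = 1e8),
                            iters = 3000, burnin = 500, seed = 123,
                            center = TRUE)
  bhat <- colMeans(poolChains(fit)[, paste0("beta_", snpIds(d$Z))])
  expect_lt(max(abs(bhat)), 0.01)
})

test_that("multi-chain LASSO shrink factor declines towards 1", {
  d <- tinyData(n = 120, p = 30, nQtl = 5, h2 = 0.5, gseed = 131,
                pseed = 132)
  fit <- bayesianLassoGibbs(d$Z, d$y, iters = 4500, burnin = 0, seed = 133,
                            chains = 10)
  ser <- psrfSeries(fit, "sigma2_e", c(500, 1500, 4500))
  expect_true(all(diff(ser$rhat) <= 0))
  expect_lt(ser$rhat[3], 1.2)
})

test_that("sampler runs inside the engine stay bit-reproducible", {
  d <- tinyData(n = 40, p = 8, gseed = 141, pseed = 142)
  a <- bayesCPiGibbs(d$Z, d$y, iters = 300, burnin = 100, seed = 9,
                     chains = 3)
  b <- bayesCPiGibbs(d$Z, d$y, iters = 300, burnin = 100, seed = 9,
                     chains = 3, workers = 2)
  expect_identical(chainDraws(a), chainDraws(b))
  l1 <- bayesianLassoGibbs(d$Z, d$y, iters = 200, burnin = 50, seed = 10)
  l2 <- bayesianLassoGibbs(d$Z, d$y, iters = 200, burnin = 50, seed = 10)
  expect_identical(chainDraws(l1), chainDraws(l2))
})
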