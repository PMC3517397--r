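## Gibbs samplers for whole-genome regression: BayesC-pi (spike-and-slab
## with unknown mixing proportion), BayesC with fixed pi, and the Bayesian
## LASSO. The marker sweeps run in compiled code (src/sweeps.cpp) but draw
## from R's RNG, so the engine's stream discipline applies unchanged.

#' Hyperparameters for the BayesC samplers
#'
#' Defaults follow common BayesC practice: `nuAlpha = nuE = 4`; the
#' effect-variance prior scale is set by an R-squared-style rule that
#' attributes half of the phenotypic variance to markers,
#' `S2Alpha = 0.5 * var(y) * (nuAlpha - 2) / nuAlpha /
#' (0.5 * sum(2 * p_j * (1 - p_j)))` with `p_j` the observed allele
#' frequencies, and `S2E = 0.5 * var(y) * (nuE - 2) / nuE`. Data-derived
#' defaults are filled in by the samplers when `S2Alpha`/`S2E` are `NULL`.
#'
#' @param nuAlpha Prior degrees of freedom of the effect variance, > 0.
#' @param S2Alpha Prior scale of the effect variance (effect units
#'   squared), or `NULL` to derive from the data.
#' @param nuE Prior degrees of freedom of the residual variance, >= 0
#'   (0 gives the vague variance prior proportional to 1/sigma2).
#' @param S2E Prior scale of the residual variance, or `NULL` to derive.
#' @param piFixed Optional fixed value of pi (the prior probability that a
#'   SNP effect is null) in \[0, 1\]; `NULL` means pi is inferred under a
#'   uniform prior.
#' @param fixSigma2Alpha,fixSigma2E Optional values at which to hold the
#'   variance components fixed (used for conjugate-oracle checks).
#' @return A list of class `"BayesCHyper"`.
#' @export
bayesCHyper <- function(nuAlpha = 4, S2Alpha = NULL, nuE = 4, S2E = NULL,
                        piFixed = NULL, fixSigma2Alpha = NULL,
                        fixSigma2E = NULL) {
  stopifnot(nuAlpha > 0, nuE >= 0)
  if (!is.null(S2Alpha)) stopifnot(S2Alpha > 0)
  if (!is.null(S2E)) stopifnot(S2E > 0)
  if (!is.null(piFixed)) stopifnot(piFixed >= 0, piFixed <= 1)
  if (!is.null(fixSigma2Alpha)) stopifnot(fixSigma2Alpha > 0)
  if (!is.null(fixSigma2E)) stopifnot(fixSigma2E > 0)
  structure(list(nuAlpha = nuAlpha, S2Alpha = S2Alpha, nuE = nuE, S2E = S2E,
                 piFixed = piFixed, fixSigma2Alpha = fixSigma2Alpha,
                 fixSigma2E = fixSigma2E),
            class = "BayesCHyper")
}

#' Hyperparameters for the Bayesian LASSO
#'
#' Marker effects follow the exponential-mixture (double-exponential)
#' hierarchy `beta_j | tau2_j, sigma2_e ~ N(0, tau2_j * sigma2_e)`,
#' `tau2_j ~ Exp(lambda2 / 2)`, with a Gamma prior on the squared
#' regularization parameter `lambda2`.
#'
#' @param lambda2Shape,lambda2Rate Shape and rate of the Gamma prior on
#'   `lambda2`, > 0.
#' @param nuE,S2E Residual-variance prior as in [bayesCHyper()].
#' @param fixLambda2 Optional fixed value of `lambda2`.
#' @param fixTau2 Optional common fixed value for all `tau2_j` (ridge
#'   limit, used by oracle checks).
#' @param fixSigma2E Optional fixed residual variance.
#' @return A list of class `"LassoHyper"`.
#' @export
lassoHyper <- function(lambda2Shape = 1, lambda2Rate = 1, nuE = 4,
                       S2E = NULL, fixLambda2 = NULL, fixTau2 = NULL,
                       fixSigma2E = NULL) {
  stopifnot(lambda2Shape > 0, lambda2Rate > 0, nuE >= 0)
  if (!is.null(S2E)) stopifnot(S2E > 0)
  if (!is.null(fixLambda2)) stopifnot(fixLambda2 > 0)
  if (!is.null(fixTau2)) stopifnot(fixTau2 > 0)
  if (!is.null(fixSigma2E)) stopifnot(fixSigma2E > 0)
  structure(list(lambda2Shape = lambda2Shape, lambda2Rate = lambda2Rate,
                 nuE = nuE, S2E = S2E, fixLambda2 = fixLambda2,
                 fixTau2 = fixTau2, fixSigma2E = fixSigma2E),
            class = "LassoHyper")
}

checkRegressionData <- function(Z, y) {
  stopifnot(is(Z, "GenotypeMatrix"))
  if (nSnp(Z) == 0) stop("no SNPs in the genotype matrix")
  if (nInd(Z) != length(y))
    stop("rows of the genotype matrix must match the phenotype length")
  if (length(y) && any(!is.finite(y))) stop("non-finite phenotypes")
}

fillHyperBayesC <- function(hyper, y, Zmat) {
  if (is.null(hyper)) hyper <- bayesCHyper()
  stopifnot(inherits(hyper, "BayesCHyper"))
  if (is.null(hyper$S2E) || is.null(hyper$S2Alpha)) {
    if (length(y) < 2)
      stop("data-derived hyperparameter defaults require n >= 2; ",
           "supply S2Alpha and S2E explicitly")
    vy <- var(y)
    if (is.null(hyper$S2E))
      hyper$S2E <- if (hyper$nuE > 2) 0.5 * vy * (hyper$nuE - 2) / hyper$nuE
                   else 0.5 * vy
    if (is.null(hyper$S2Alpha)) {
      phat <- colMeans(Zmat) / 2
      het <- sum(2 * phat * (1 - phat))
      denom <- 0.5 * het
      if (denom <= 0) denom <- 1 # monomorphic panel: fall back to unit mass
      hyper$S2Alpha <- 0.5 * vy * (hyper$nuAlpha - 2) / hyper$nuAlpha / denom
      if (hyper$S2Alpha <= 0) hyper$S2Alpha <- 0.5 * vy / denom
    }
  }
  hyper
}

bayesCKernel <- function(Zmat, y, hyper, fixMu) {
  n <- length(y)
  p <- ncol(Zmat)
  csum <- colSums(Zmat^2)
  ids <- colnames(Zmat)
  updatePi <- is.null(hyper$piFixed)
  fixS2a <- !is.null(hyper$fixSigma2Alpha)
  fixS2e <- !is.null(hyper$fixSigma2E)
  fixMu <- fixMu || n == 0
  list(
    init = function() {
      mu <- if (fixMu) 0 else rnorm(1, mean(y), max(sd(y), 1e-8))
      s2a <- if (fixS2a) hyper$fixSigma2Alpha
             else hyper$nuAlpha * hyper$S2Alpha / rchisq(1, hyper$nuAlpha)
      s2e <- if (fixS2e) hyper$fixSigma2E
             else if (hyper$nuE > 0)
               hyper$nuE * hyper$S2E / rchisq(1, hyper$nuE)
             else hyper$S2E # vague prior has no proper draw; start at scale
      pi0 <- if (updatePi) runif(1) else hyper$piFixed
      list(mu = mu, alpha = numeric(p), delta = integer(p), pi = pi0,
           s2a = s2a, s2e = s2e, e = y - mu)
    },
    step = function(state) {
      .bayesc_sweep(Zmat, state$e, state$mu, state$alpha, state$delta,
                    state$pi, state$s2a, state$s2e, csum,
                    hyper$nuAlpha, hyper$S2Alpha, hyper$nuE, hyper$S2E,
                    updatePi, fixMu, fixS2a, fixS2e)
    },
    monitor = function(state) {
      c(mu = state$mu, pi = state$pi, sigma2_alpha = state$s2a,
        sigma2_e = state$s2e,
        setNames(state$alpha, paste0("alpha_", ids)),
        setNames(as.numeric(state$delta), paste0("delta_", ids)))
    })
}

#' BayesC-pi Gibbs sampler
#'
#' Spike-and-slab whole-genome regression: `y = 1*mu + Z*alpha + e`, where
#' each SNP effect is null with probability `pi` or drawn from
#' `N(0, sigma2_alpha)` otherwise; `pi` carries a uniform prior and both
#' variance components carry scaled inverse-chi-squared priors. One Gibbs
#' sweep updates `mu`, then each `(delta_j, alpha_j)` with the indicator
#' marginalized over the effect, then `sigma2_alpha`, `sigma2_e` and `pi`
#' (`pi | delta ~ Beta(p - k + 1, k + 1)` with `k` markers in the model).
#' Genotype codes are used raw (0/1/2) unless `center = TRUE`.
#'
#' @param Z A [GenotypeMatrix-class] (n individuals x p SNPs).
#' @param y Numeric phenotype vector of length n.
#' @param hyper A [bayesCHyper()] object, or `NULL` for data-derived
#'   defaults.
#' @param iters,burnin,thin MCMC controls per chain.
#' @param seed Integer base seed; chain `i` uses stream `(seed, i)`.
#' @param chains Number of independent chains.
#' @param workers Scheduling parallelism (never changes the result).
#' @param center Center genotype columns before fitting.
#' @param fixMu Hold the intercept at 0 (forced when n = 0, where the
#'   flat-prior intercept update is improper).
#' @return A [BayesCResult-class]. PIPs are the pooled means of the
#'   retained indicator draws.
#' @examples
#' Z <- simulateGenotypes(60, 30, c(0.2, 0.5), seed = 1)
#' sim <- simulatePhenotypes(Z, nQtl = 3, h2 = 0.6, seed = 2)
#' fit <- bayesCPiGibbs(Z, sim$y, iters = 200, burnin = 100, seed = 3)
#' head(sort(pip(fit), decreasing = TRUE))
#' @export
bayesCPiGibbs <- function(Z, y, hyper = NULL, iters = 1000L, burnin = 0L,
                          thin = 1L, seed = 1L, chains = 1L, workers = 1L,
                          center = FALSE, fixMu = FALSE) {
  checkRegressionData(Z, y)
  Zmat <- genotypes(Z)
  centers <- rep(0, ncol(Zmat))
  if (center && nrow(Zmat)) {
    centers <- colMeans(Zmat)
    Zmat <- sweep(Zmat, 2L, centers)
  }
  hyper <- fillHyperBayesC(hyper, y, genotypes(Z))
  kernel <- bayesCKernel(Zmat, y, hyper, fixMu)
  mc <- runMultiChain(kernel, chains = chains, iters = iters,
                      burnin = burnin, thin = thin, baseSeed = seed,
                      workers = workers)
  pooled <- poolChains(mc)
  dcols <- paste0("delta_", colnames(Zmat))
  pipv <- colMeans(pooled[, dcols, drop = FALSE])
  new("BayesCResult", chains = mc,
      pip = setNames(as.numeric(pipv), colnames(Zmat)),
      snpIds = colnames(Zmat), center = center, centers = centers)
}

#' BayesC sampler with fixed pi
#'
#' The same model and sweep as [bayesCPiGibbs()] with `pi` held at a fixed
#' value (default 0: every marker has a non-null effect, the model used for
#' post-feature-selection inference). This is literally the BayesC-pi code
#' path with `piFixed` set, so the two are draw-for-draw identical at equal
#' seeds.
#'
#' @inheritParams bayesCPiGibbs
#' @param pi Fixed value of pi in \[0, 1\].
#' @return A [BayesCResult-class].
#' @export
bayesCFixedPiGibbs <- function(Z, y, hyper = NULL, iters = 1000L,
                               burnin = 0L, thin = 1L, seed = 1L, pi = 0,
                               chains = 1L, workers = 1L, center = FALSE,
                               fixMu = FALSE) {
  hyper <- fillHyperBayesC(hyper, y, genotypes(Z))
  hyper$piFixed <- pi
  bayesCPiGibbs(Z, y, hyper, iters = iters, burnin = burnin, thin = thin,
                seed = seed, chains = chains, workers = workers,
                center = center, fixMu = fixMu)
}

#' @describeIn predictGEBV Posterior-mean intercept plus genotype codes
#'   times posterior-mean effects (training centering, if any, is applied
#'   to the new genotypes).
setMethod("predictGEBV", signature("BayesCResult", "GenotypeMatrix"),
  function(object, newdata) {
    if (!identical(snpIds(newdata), object@snpIds))
      stop("SNP set/order of 'newdata' does not match the training set")
    pooled <- poolChains(object@chains)
    muHat <- mean(pooled[, "mu"])
    aHat <- colMeans(pooled[, paste0("alpha_", object@snpIds),
                            drop = FALSE])
    Zn <- genotypes(newdata)
    if (object@center) Zn <- sweep(Zn, 2L, object@centers)
    as.numeric(muHat + Zn %*% aHat)
  })

#' Bayesian LASSO Gibbs sampler
#'
#' Whole-genome regression `y = 1*mu + X*beta + e` with double-exponential
#' shrinkage on the marker effects via the scale-mixture representation
#' (see [lassoHyper()]). One sweep updates `mu`, each `beta_j`, each
#' `tau2_j` (inverse-Gaussian draw for `1/tau2_j`), `lambda2`, and
#' `sigma2_e`. Residual-variance draws are monitored as `sigma2_e` for
#' multi-chain convergence diagnosis.
#'
#' @inheritParams bayesCPiGibbs
#' @param X A [GenotypeMatrix-class] of marker covariates.
#' @param hyper A [lassoHyper()] object, or `NULL` for defaults.
#' @return A [MultiChainResult-class] monitoring `mu`, `lambda2`,
#'   `sigma2_e` and the `beta_j`.
#' @export
bayesianLassoGibbs <- function(X, y, hyper = NULL, iters = 1000L,
                               burnin = 0L, thin = 1L, seed = 1L,
                               chains = 1L, workers = 1L, center = FALSE,
                               fixMu = FALSE) {
  checkRegressionData(X, y)
  Xmat <- genotypes(X)
  if (center && nrow(Xmat)) Xmat <- sweep(Xmat, 2L, colMeans(Xmat))
  if (is.null(hyper)) hyper <- lassoHyper()
  stopifnot(inherits(hyper, "LassoHyper"))
  if (is.null(hyper$S2E)) {
    if (length(y) < 2)
      stop("data-derived hyperparameter defaults require n >= 2; ",
           "supply S2E explicitly")
    hyper$S2E <- if (hyper$nuE > 2)
      0.5 * var(y) * (hyper$nuE - 2) / hyper$nuE else 0.5 * var(y)
  }
  n <- length(y)
  p <- ncol(Xmat)
  csum <- colSums(Xmat^2)
  ids <- colnames(Xmat)
  fixMu <- fixMu || n == 0
  fixTau2 <- !is.null(hyper$fixTau2)
  fixLambda2 <- !is.null(hyper$fixLambda2)
  fixS2e <- !is.null(hyper$fixSigma2E)
  kernel <- list(
    init = function() {
      mu <- if (fixMu) 0 else rnorm(1, mean(y), max(sd(y), 1e-8))
      lambda2 <- if (fixLambda2) hyper$fixLambda2
                 else rgamma(1, hyper$lambda2Shape, rate = hyper$lambda2Rate)
      tau2 <- if (fixTau2) rep(hyper$fixTau2, p)
              else rexp(p, rate = lambda2 / 2)
      s2e <- if (fixS2e) hyper$fixSigma2E
             else if (hyper$nuE > 0)
               hyper$nuE * hyper$S2E / rchisq(1, hyper$nuE)
             else hyper$S2E
      list(mu = mu, beta = numeric(p), tau2 = tau2, lambda2 = lambda2,
           s2e = s2e, e = y - mu)
    },
    step = function(state) {
      .blasso_sweep(Xmat, state$e, state$mu, state$beta, state$tau2,
                    state$lambda2, state$s2e, csum, hyper$lambda2Shape,
                    hyper$lambda2Rate, hyper$nuE, hyper$S2E, fixMu,
                    fixTau2, fixLambda2, fixS2e)
    },
    monitor = function(state) {
      c(mu = state$mu, lambda2 = state$lambda2, sigma2_e = state$s2e,
        setNames(state$beta, paste0("beta_", ids)))
    })
  runMultiChain(kernel, chains = chains, iters = iters, burnin = burnin,
                thin = thin, baseSeed = seed, workers = workers)
}
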