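## Central S4 classes. Small distribution objects are plain value classes;
## sampler output wraps per-chain draw matrices.

#' NormalPosterior: closed-form normal posterior of a mean
#'
#' Posterior of the mean of a normal model with known variance, obtained by
#' combining a normal prior with the sample mean at their respective
#' precisions.
#'
#' @slot mean Posterior mean (trait units).
#' @slot variance Posterior variance (trait units squared), non-negative.
#' @seealso [posteriorMeanKnownVariance()]
#' @export
setClass("NormalPosterior",
  representation(mean = "numeric", variance = "numeric"),
  validity = function(object) {
    if (length(object@mean) != 1L || length(object@variance) != 1L)
      return("mean and variance must be scalars")
    if (!is.finite(object@mean) || !is.finite(object@variance))
      return("mean and variance must be finite")
    if (object@variance < 0) return("variance must be >= 0")
    TRUE
  })

#' ScaledInvChi2: scaled inverse-chi-squared distribution
#'
#' Conjugate posterior (and prior) family for normal variances. A draw is
#' `df * scale / rchisq(1, df)`.
#'
#' @slot df Degrees of freedom, > 0.
#' @slot scale Scale parameter (variance units), >= 0.
#' @seealso [posteriorVarianceKnownMean()]
#' @export
setClass("ScaledInvChi2",
  representation(df = "numeric", scale = "numeric"),
  validity = function(object) {
    if (length(object@df) != 1L || length(object@scale) != 1L)
      return("df and scale must be scalars")
    if (!is.finite(object@df) || object@df <= 0) return("df must be > 0")
    if (!is.finite(object@scale) || object@scale < 0)
      return("scale must be >= 0")
    TRUE
  })

#' StudentTPosterior: location-scale Student-t posterior
#'
#' Marginal posterior of a normal mean when the variance is unknown
#' (integrated out under the vague joint prior).
#'
#' @slot df Degrees of freedom, > 0.
#' @slot center Location (trait units).
#' @slot scale2 Squared scale (trait units squared), > 0.
#' @seealso [twoParamMarginals()]
#' @export
setClass("StudentTPosterior",
  representation(df = "numeric", center = "numeric", scale2 = "numeric"),
  validity = function(object) {
    if (!is.finite(object@df) || object@df <= 0) return("df must be > 0")
    if (!is.finite(object@center)) return("center must be finite")
    if (!is.finite(object@scale2) || object@scale2 <= 0)
      return("scale2 must be > 0")
    TRUE
  })

#' GenotypeMatrix: individuals-by-SNP additive genotype codes
#'
#' A numeric matrix of additive genotype codes (0/1/2 copies of the counted
#' allele; possibly fractional after mean imputation) with individual IDs as
#' row names and SNP IDs as column names.
#'
#' @slot geno Numeric matrix, values in \[0, 2\], rows = individuals,
#'   columns = SNPs.
#' @seealso [readGenotypes()], [simulateGenotypes()]
#' @export
setClass("GenotypeMatrix",
  representation(geno = "matrix"),
  validity = function(object) {
    g <- object@geno
    if (!is.numeric(g)) return("genotype codes must be numeric")
    if (anyNA(g)) return("genotype matrix contains missing codes")
    if (length(g) && (min(g) < 0 || max(g) > 2))
      return("genotype codes must lie in [0, 2]")
    if (is.null(colnames(g)) && ncol(g) > 0)
      return("SNP ids (column names) are required")
    if (anyDuplicated(colnames(g))) return("duplicate SNP ids")
    if (!is.null(rownames(g)) && anyDuplicated(rownames(g)))
      return("duplicate individual ids")
    TRUE
  })

#' ChainSamples: retained draws of one MCMC chain
#'
#' @slot draws Matrix, retained iterations in rows, monitored parameters in
#'   columns (named).
#' @slot burnin Number of discarded initial iterations.
#' @slot thin Thinning interval (>= 1).
#' @slot seed Base seed of the run the chain belongs to.
#' @slot chainId Chain index (also the RNG stream id).
#' @export
setClass("ChainSamples",
  representation(draws = "matrix", burnin = "integer", thin = "integer",
                 seed = "integer", chainId = "integer"),
  validity = function(object) {
    if (is.null(colnames(object@draws))) return("draws must have column names")
    if (anyDuplicated(colnames(object@draws)))
      return("parameter names must be unique")
    if (object@thin < 1L) return("thin must be >= 1")
    if (object@burnin < 0L) return("burnin must be >= 0")
    TRUE
  })

#' MultiChainResult: draws from several independent chains
#'
#' All chains share the same monitored parameters and number of retained
#' draws; they differ only in their RNG stream (and hence their trajectory).
#'
#' @slot chains List of [ChainSamples-class] objects.
#' @export
setClass("MultiChainResult",
  representation(chains = "list"),
  validity = function(object) {
    if (!length(object@chains)) return("at least one chain is required")
    if (!all(vapply(object@chains, is, logical(1), "ChainSamples")))
      return("chains must be ChainSamples objects")
    nm <- lapply(object@chains, function(ch) colnames(ch@draws))
    nr <- vapply(object@chains, function(ch) nrow(ch@draws), integer(1))
    if (!all(vapply(nm, identical, logical(1), nm[[1]])))
      return("all chains must monitor the same parameters")
    if (length(unique(nr)) != 1L)
      return("all chains must have the same number of retained draws")
    TRUE
  })

#' BayesCResult: posterior draws and inclusion probabilities
#'
#' Output of the BayesC-pi (or fixed-pi) Gibbs sampler: multi-chain draws of
#' the intercept, pi, the two variance components, the per-SNP effects and
#' indicators, plus the per-SNP posterior inclusion probabilities (PIPs,
#' the mean of the retained indicator draws pooled over chains).
#'
#' @slot chains A [MultiChainResult-class].
#' @slot pip Named numeric vector of posterior inclusion probabilities.
#' @slot snpIds Character vector of SNP ids (training order).
#' @slot center Logical; were genotype columns centered before fitting.
#' @slot centers Column means subtracted when `center = TRUE` (else zeros).
#' @export
setClass("BayesCResult",
  representation(chains = "MultiChainResult", pip = "numeric",
                 snpIds = "character", center = "logical",
                 centers = "numeric"),
  validity = function(object) {
    if (length(object@pip) != length(object@snpIds))
      return("one PIP per SNP required")
    if (length(object@pip) && (min(object@pip) < 0 || max(object@pip) > 1))
      return("PIPs must lie in [0, 1]")
    TRUE
  })

#' CVReport: K-fold cross-validation accuracies for one SNP panel
#'
#' @slot panelSize Number of SNPs in the panel.
#' @slot snpIds SNP ids of the panel.
#' @slot foldId Integer fold assignment of each individual.
#' @slot fitCor Per-fold fitting accuracy (train-set correlation).
#' @slot predCor Per-fold predictive accuracy (test-set correlation); may be
#'   NA for degenerate folds.
#' @slot meanFit Mean fitting accuracy over defined folds.
#' @slot meanPred Mean predictive accuracy over defined folds (for
#'   leave-one-out style folds, the pooled-prediction correlation).
#' @slot pooledPredCor Correlation of the pooled out-of-fold predictions
#'   with the phenotypes (NA unless computed).
#' @export
setClass("CVReport",
  representation(panelSize = "integer", snpIds = "character",
                 foldId = "integer", fitCor = "numeric", predCor = "numeric",
                 meanFit = "numeric", meanPred = "numeric",
                 pooledPredCor = "numeric"),
  validity = function(object) {
    ok <- function(x) !length(x) || all(is.na(x) | (x >= -1 & x <= 1))
    if (!ok(object@fitCor) || !ok(object@predCor))
      return("correlations must lie in [-1, 1]")
    if (object@panelSize != length(object@snpIds))
      return("panelSize must equal the number of SNP ids")
    tab <- tabulate(object@foldId)
    tab <- tab[tab > 0]
    if (length(tab) && diff(range(tab)) > 1L)
      return("folds must be sized within one of each other")
    TRUE
  })

#' PipelineReport: result of a BayesCpC panel-search run
#'
#' @slot strategy One of "I", "II", "III".
#' @slot pips Feature-selection PIP table(s): a list with one data.frame per
#'   panel (strategies I/III) or a single-element list (strategy II).
#' @slot reports List of [CVReport-class], one per panel size.
#' @slot panelSizes Integer vector of panel sizes examined.
#' @slot fsSeeds Integer vector of the feature-selection seed used per panel
#'   (provenance; identical entries mean one shared ranking).
#' @slot optimalSize Panel size with peak mean predictive accuracy.
#' @slot timings Named numeric, informational wall-times per stage.
#' @export
setClass("PipelineReport",
  representation(strategy = "character", pips = "list", reports = "list",
                 panelSizes = "integer", fsSeeds = "integer",
                 optimalSize = "integer", timings = "numeric"),
  validity = function(object) {
    if (!object@strategy %in% c("I", "II", "III"))
      return("strategy must be one of I, II, III")
    if (length(object@reports) != length(object@panelSizes))
      return("one CVReport per panel size required")
    TRUE
  })

#' SimTruth: known genetic architecture of a simulated phenotype
#'
#' @slot qtlIndices Column indices of the causal SNPs.
#' @slot qtlEffects Allele substitution effects of the causal SNPs.
#' @slot tbv True breeding values (genetic values) per individual.
#' @slot realizedH2 Realized heritability var(g) / (var(g) + var(e)) on the
#'   simulated sample.
#' @export
setClass("SimTruth",
  representation(qtlIndices = "integer", qtlEffects = "numeric",
                 tbv = "numeric", realizedH2 = "numeric"),
  validity = function(object) {
    if (length(object@qtlIndices) != length(object@qtlEffects))
      return("one effect per QTL required")
    if (object@realizedH2 < 0 || object@realizedH2 > 1)
      return("realizedH2 must lie in [0, 1]")
    TRUE
  })

## ---- show methods -------------------------------------------------------

setMethod("show", "NormalPosterior", function(object) {
  cat(sprintf("NormalPosterior(mean = %.6g, variance = %.6g)\n",
              object@mean, object@variance))
})

setMethod("show", "ScaledInvChi2", function(object) {
  m <- if (object@df > 2) object@df * object@scale / (object@df - 2) else NA
  cat(sprintf("ScaledInvChi2(df = %.4g, scale = %.6g)%s\n", object@df,
              object@scale,
              if (is.na(m)) " [expectation undefined: df <= 2]"
              else sprintf(", mean = %.6g", m)))
})

setMethod("show", "StudentTPosterior", function(object) {
  cat(sprintf("StudentTPosterior(df = %.4g, center = %.6g, scale2 = %.6g)\n",
              object@df, object@center, object@scale2))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs\n",
              nrow(object@geno), ncol(object@geno)))
  if (ncol(object@geno)) {
    p <- colMeans(object@geno) / 2
    cat(sprintf("  allele frequency range: [%.3f, %.3f]\n", min(p), max(p)))
  }
})

setMethod("show", "ChainSamples", function(object) {
  cat(sprintf(
    "ChainSamples: chain %d, %d retained draws of %d parameters (burnin %d, thin %d)\n",
    object@chainId, nrow(object@draws), ncol(object@draws), object@burnin,
    object@thin))
})

setMethod("show", "MultiChainResult", function(object) {
  ch <- object@chains[[1]]
  cat(sprintf("MultiChainResult: %d chains x %d retained draws, %d parameters\n",
              length(object@chains), nrow(ch@draws), ncol(ch@draws)))
})

setMethod("show", "BayesCResult", function(object) {
  show(object@chains)
  cat(sprintf("  %d SNPs; top PIP = %.3f (%s)\n", length(object@pip),
              max(object@pip), object@snpIds[which.max(object@pip)]))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf(
    "CVReport: panel of %d SNPs, %d folds; fit = %.4f, pred = %.4f\n",
    object@panelSize, length(object@fitCor), object@meanFit,
    object@meanPred))
})

setMethod("show", "PipelineReport", function(object) {
  cat(sprintf(
    "PipelineReport (strategy %s): %d panels, optimal size %d\n",
    object@strategy, length(object@reports), object@optimalSize))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d QTL, realized h2 = %.4f\n",
              length(object@qtlIndices), object@realizedH2))
})
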