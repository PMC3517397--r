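#' Draw random samples from a closed-form posterior
#'
#' @param object A distribution object ([NormalPosterior-class],
#'   [ScaledInvChi2-class] or [StudentTPosterior-class]).
#' @param n Number of draws.
#' @return Numeric vector of `n` draws, generated from the current RNG
#'   state (seed it, or use it as the sampler of [parallelMonteCarlo()]).
#' @export
setGeneric("rposterior", function(object, n) standardGeneric("rposterior"))

#' Posterior expectation of a distribution object
#'
#' For [ScaledInvChi2-class], the expectation `df * scale / (df - 2)` is
#' only defined for `df > 2`; otherwise `NA` is returned with a warning.
#'
#' @param object A distribution object.
#' @return Scalar expectation (or `NA` if undefined).
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))

#' Posterior variance of a distribution object
#'
#' @param object A distribution object.
#' @return Scalar variance (or `NA` if undefined).
#' @export
setGeneric("posteriorVariance",
           function(object) standardGeneric("posteriorVariance"))

#' Number of individuals
#' @param object A [GenotypeMatrix-class].
#' @return Integer count.
#' @export
setGeneric("nInd", function(object) standardGeneric("nInd"))

#' Number of SNPs
#' @param object A [GenotypeMatrix-class].
#' @return Integer count.
#' @export
setGeneric("nSnp", function(object) standardGeneric("nSnp"))

#' SNP identifiers
#' @param object A [GenotypeMatrix-class] or [BayesCResult-class].
#' @return Character vector of SNP ids.
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))

#' Individual identifiers
#' @param object A [GenotypeMatrix-class].
#' @return Character vector of individual ids.
#' @export
setGeneric("indIds", function(object) standardGeneric("indIds"))

#' Genotype codes as a plain matrix
#' @param object A [GenotypeMatrix-class].
#' @return Numeric matrix (individuals x SNPs).
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' Retained draws
#'
#' @param object A [ChainSamples-class], [MultiChainResult-class] or
#'   [BayesCResult-class].
#' @param ... Passed on to methods.
#' @return For a single chain, its draw matrix; for multi-chain objects, the
#'   list of per-chain draw matrices.
#' @export
setGeneric("chainDraws", function(object, ...) standardGeneric("chainDraws"))

#' Monitored parameter names
#' @param object A draws container.
#' @return Character vector.
#' @export
setGeneric("parameterNames",
           function(object) standardGeneric("parameterNames"))

#' Number of chains
#' @param object A multi-chain container.
#' @return Integer count.
#' @export
setGeneric("nChains", function(object) standardGeneric("nChains"))

#' Posterior inclusion probabilities
#' @param object A [BayesCResult-class].
#' @return Named numeric vector, one PIP per SNP.
#' @export
setGeneric("pip", function(object) standardGeneric("pip"))

#' Predict genomic estimated breeding values
#'
#' @param object A fitted [BayesCResult-class].
#' @param newdata A [GenotypeMatrix-class] with the same SNP set and order
#'   as the training genotypes.
#' @return Numeric vector: posterior-mean intercept plus `Z %*%`
#'   posterior-mean effects.
#' @export
setGeneric("predictGEBV",
           function(object, newdata) standardGeneric("predictGEBV"))

#' Write result files for a run
#'
#' @param object A result object (multi-chain draws, BayesC fit, or
#'   pipeline report).
#' @param outdir Output directory (created if missing).
#' @param ... Passed on to methods.
#' @return Invisibly, the character vector of files written.
#' @export
setGeneric("writeReports",
           function(object, outdir, ...) standardGeneric("writeReports"))
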