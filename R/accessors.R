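## Accessor methods for the data containers.

#' Construct a GenotypeMatrix
#'
#' @param geno Numeric matrix of additive codes in \[0, 2\], individuals in
#'   rows, SNPs in columns. Column names become SNP ids (generated as
#'   `snp1..snpP` if absent); row names become individual ids.
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(geno) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (is.null(colnames(geno)) && ncol(geno))
    colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  if (is.null(rownames(geno)) && nrow(geno))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  new("GenotypeMatrix", geno = geno)
}

#' @describeIn GenotypeMatrix Number of individuals.
setMethod("nInd", "GenotypeMatrix", function(object) nrow(object@geno))

#' @describeIn GenotypeMatrix Number of SNPs.
setMethod("nSnp", "GenotypeMatrix", function(object) ncol(object@geno))

#' @describeIn GenotypeMatrix SNP ids.
setMethod("snpIds", "GenotypeMatrix", function(object) colnames(object@geno))

#' @describeIn GenotypeMatrix Individual ids.
setMethod("indIds", "GenotypeMatrix", function(object) rownames(object@geno))

#' @describeIn GenotypeMatrix The underlying code matrix.
setMethod("genotypes", "GenotypeMatrix", function(object) object@geno)

#' Subset a GenotypeMatrix
#'
#' @param x A [GenotypeMatrix-class].
#' @param i Individual (row) index.
#' @param j SNP (column) index or ids.
#' @param ... Ignored.
#' @param drop Ignored (never drops).
#' @return A [GenotypeMatrix-class].
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  g <- x@geno
  if (!missing(i)) g <- g[i, , drop = FALSE]
  if (!missing(j)) g <- g[, j, drop = FALSE]
  new("GenotypeMatrix", geno = g)
})

#' @describeIn chainDraws The draw matrix of one chain.
setMethod("chainDraws", "ChainSamples", function(object, ...) object@draws)

#' @describeIn chainDraws List of per-chain draw matrices.
setMethod("chainDraws", "MultiChainResult", function(object, ...)
  lapply(object@chains, function(ch) ch@draws))

#' @describeIn chainDraws Per-chain draw matrices of the sampler run.
setMethod("chainDraws", "BayesCResult", function(object, ...)
  chainDraws(object@chains))

setMethod("parameterNames", "ChainSamples",
          function(object) colnames(object@draws))
setMethod("parameterNames", "MultiChainResult",
          function(object) colnames(object@chains[[1]]@draws))
setMethod("parameterNames", "BayesCResult",
          function(object) parameterNames(object@chains))

setMethod("nChains", "MultiChainResult",
          function(object) length(object@chains))
setMethod("nChains", "BayesCResult", function(object) nChains(object@chains))

#' @describeIn pip The PIP vector.
setMethod("pip", "BayesCResult", function(object) object@pip)

#' @describeIn snpIds SNP ids of a fitted BayesC model.
setMethod("snpIds", "BayesCResult", function(object) object@snpIds)
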