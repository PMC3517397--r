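## The BayesCpC workflow: BayesC-pi feature selection, nested top-X SNP
## panels, BayesC(pi = 0) refitting under K-fold cross-validation, and the
## three execution strategies for searching the optimal panel size.

#' Pipeline configuration
#'
#' Bundles the MCMC settings of the feature-selection (FS) and
#' cross-validation (CV) stages.
#'
#' @param fsIters,fsBurnin,fsThin,fsChains FS-stage MCMC controls (the FS
#'   run pools PIPs over `fsChains` chains).
#' @param cvIters,cvBurnin,cvThin CV-stage MCMC controls for the
#'   BayesC(pi = 0) refits.
#' @param folds Number of CV folds, >= 2.
#' @param hyper Optional [bayesCHyper()] shared by both stages.
#' @param center Center genotype columns in both stages.
#' @param workers Scheduling parallelism.
#' @param fsSeedPolicy `"shared"` (one FS ranking reused by every panel;
#'   the default, under which strategies I and II coincide result-wise) or
#'   `"perPanel"` (each panel's meta-job draws its own FS seed, as in
#'   fully independent meta-jobs).
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(fsIters = 1000L, fsBurnin = 200L, fsThin = 1L,
                           fsChains = 3L, cvIters = 1000L, cvBurnin = 200L,
                           cvThin = 1L, folds = 3L, hyper = NULL,
                           center = FALSE, workers = 1L,
                           fsSeedPolicy = c("shared", "perPanel")) {
  fsSeedPolicy <- match.arg(fsSeedPolicy)
  stopifnot(folds >= 2)
  structure(list(fsIters = fsIters, fsBurnin = fsBurnin, fsThin = fsThin,
                 fsChains = fsChains, cvIters = cvIters,
                 cvBurnin = cvBurnin, cvThin = cvThin, folds = folds,
                 hyper = hyper, center = center, workers = workers,
                 fsSeedPolicy = fsSeedPolicy),
            class = "PipelineConfig")
}

#' Feature selection by BayesC-pi posterior inclusion probability
#'
#' Runs `nChains` BayesC-pi chains through the engine and ranks SNPs by
#' their pooled PIP (mean of retained indicator draws over all chains).
#' Ties are broken by ascending SNP index so the ranking is stable.
#'
#' @param Z A [GenotypeMatrix-class].
#' @param y Phenotypes.
#' @param cfg A [pipelineConfig()] (its FS settings are used).
#' @param nChains Number of FS chains (overrides `cfg$fsChains` if given).
#' @param seed Integer base seed of the FS run.
#' @return A PIP table: data frame with columns `snp_id`, `pip`, `rank`,
#'   ordered by rank (1 = highest PIP).
#' @export
featureSelect <- function(Z, y, cfg = pipelineConfig(), nChains = NULL,
                          seed = 1L) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(nChains)) nChains <- cfg$fsChains
  fit <- bayesCPiGibbs(Z, y, hyper = cfg$hyper, iters = cfg$fsIters,
                       burnin = cfg$fsBurnin, thin = cfg$fsThin,
                       seed = seed, chains = nChains,
                       workers = cfg$workers, center = cfg$center)
  pipTable(pip(fit))
}

## PIP vector -> ranked table (ties broken by ascending SNP index)
pipTable <- function(pipv) {
  ord <- order(-pipv, seq_along(pipv))
  data.frame(snp_id = names(pipv)[ord], pip = unname(pipv[ord]),
             rank = seq_along(pipv), stringsAsFactors = FALSE)
}

#' Build nested top-X SNP panels from a PIP table
#'
#' Panel of size `k` is the first `k` entries by rank, so panels are
#' nested: every smaller panel is a subset of every larger one.
#'
#' @param pips PIP table from [featureSelect()].
#' @param sizes Panel sizes, each `<= nrow(pips)`.
#' @return Named list of character vectors of SNP ids, one per size.
#' @examples
#' # the classic grid: top 50, then 100..3000 in steps of 100 (31 panels)
#' panelSizeGrid(3000)
#' @export
buildPanels <- function(pips, sizes) {
  stopifnot(is.data.frame(pips), all(c("snp_id", "rank") %in% names(pips)))
  sizes <- as.integer(sizes)
  if (any(sizes < 1) || any(sizes > nrow(pips)))
    stop("panel sizes must lie in [1, number of SNPs]")
  ord <- pips$snp_id[order(pips$rank)]
  setNames(lapply(sizes, function(k) ord[seq_len(k)]),
           paste0("top", sizes))
}

#' @rdname buildPanels
#' @param maxSize Largest panel size (capped at `p` when used).
#' @param p Optional number of SNPs to cap the grid at.
#' @return `panelSizeGrid()`: integer vector `c(50, 100, 200, ..., maxSize)`.
#' @export
panelSizeGrid <- function(maxSize = 3000L, p = NULL) {
  sizes <- c(50L, seq(100L, as.integer(maxSize), by = 100L))
  if (!is.null(p)) sizes <- sizes[sizes <= p]
  sizes
}

#' K-fold cross-validation of a SNP panel
#'
#' Individuals are permuted into `folds` near-equal folds from the seeded
#' stream; for each rotation a BayesC(pi = 0) model on the panel SNPs is
#' trained on the other folds. Fitting accuracy is the correlation of the
#' training phenotypes with their fitted values; predictive accuracy is
#' the correlation of the test phenotypes with their predictions. Folds in
#' which a correlation is undefined (constant phenotype, or a single
#' individual) are flagged `NA` and excluded from the means with a
#' warning; if any fold is a singleton, the pooled out-of-fold prediction
#' correlation is reported as the predictive summary instead.
#'
#' @param Z A [GenotypeMatrix-class] (all SNPs; the panel subset is taken
#'   internally).
#' @param y Phenotypes.
#' @param panel Character vector of panel SNP ids.
#' @param folds Number of folds `K >= 2` (with `n >= 2K`, or `K = n` for
#'   leave-one-out).
#' @param cfg A [pipelineConfig()] (its CV settings are used).
#' @param seed Integer seed for fold assignment and fold-wise samplers.
#' @return A [CVReport-class].
#' @export
crossvalidatePanel <- function(Z, y, panel, folds, cfg = pipelineConfig(),
                               seed = 1L) {
  stopifnot(inherits(cfg, "PipelineConfig"), is.character(panel))
  n <- nInd(Z)
  if (folds < 2) stop("'folds' must be >= 2")
  if (n < 2 * folds && folds != n)
    stop("need n >= 2 * folds (or folds = n for leave-one-out)")
  if (!all(panel %in% snpIds(Z))) stop("panel SNPs not found in genotypes")
  Zp <- Z[, panel]
  foldId <- withStream(seed, 0L, sample(rep_len(seq_len(folds), n)))
  fitCor <- predCor <- rep(NA_real_, folds)
  pooledPred <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    test <- foldId == k
    fit <- bayesCFixedPiGibbs(Zp[!test, ], y[!test], hyper = cfg$hyper,
                              iters = cfg$cvIters, burnin = cfg$cvBurnin,
                              thin = cfg$cvThin,
                              seed = deriveSeed(seed, k),
                              center = cfg$center)
    fitted <- predictGEBV(fit, Zp[!test, ])
    pred <- predictGEBV(fit, Zp[test, ])
    pooledPred[test] <- pred
    fitCor[k] <- safeCor(y[!test], fitted)
    predCor[k] <- safeCor(y[test], pred)
  }
  if (anyNA(predCor) && any(tabulate(foldId) > 1L))
    warning("some folds had undefined correlations; excluded from means")
  pooled <- if (any(tabulate(foldId) == 1L)) safeCor(y, pooledPred)
            else NA_real_
  meanPred <- if (!is.na(pooled)) pooled
              else mean(predCor, na.rm = TRUE)
  new("CVReport", panelSize = length(panel), snpIds = panel,
      foldId = as.integer(foldId), fitCor = fitCor, predCor = predCor,
      meanFit = mean(fitCor, na.rm = TRUE), meanPred = meanPred,
      pooledPredCor = pooled)
}

safeCor <- function(a, b) {
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Run the BayesCpC panel-search pipeline
#'
#' Searches a grid of top-X SNP panel sizes for the best predictive
#' accuracy under one of three execution strategies:
#' * **I** — one meta-job per panel (own FS round plus CV round),
#'   scheduled concurrently; under the default shared FS-seed policy every
#'   meta-job reproduces the same ranking.
#' * **II** — a single FS round whose ranking is reused by all panels; CV
#'   rounds run sequentially.
#' * **III** — meta-jobs in series, each with its own FS seed (so panel
#'   rankings may differ; provenance is recorded in `fsSeeds`).
#'
#' @param Z A [GenotypeMatrix-class].
#' @param y Phenotypes.
#' @param sizes Panel sizes to examine (see [panelSizeGrid()]).
#' @param strategy `"I"`, `"II"` or `"III"`.
#' @param cfg A [pipelineConfig()].
#' @param seed Integer base seed; all stage seeds derive from it.
#' @return A [PipelineReport-class].
#' @export
runPipeline <- function(Z, y, sizes, strategy = c("II", "I", "III"),
                        cfg = pipelineConfig(), seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cfg, "PipelineConfig"))
  sizes <- as.integer(sizes)
  nPanels <- length(sizes)
  if (!nPanels) stop("no panel sizes given")
  ## per-panel seeds are indexed from 0 so the first meta-job coincides
  ## with the shared ranking: a single-panel run is strategy-invariant
  fsSeedFor <- function(i) {
    if (strategy == "III" || cfg$fsSeedPolicy == "perPanel")
      deriveSeed(seed, i - 1L) else deriveSeed(seed, 0L)
  }
  cvSeedFor <- function(i) deriveSeed(seed, 1000L + i)
  t0 <- proc.time()[["elapsed"]]

  metaJob <- function(i) {
    pips <- featureSelect(Z, y, cfg, seed = fsSeedFor(i))
    panel <- buildPanels(pips, sizes[i])[[1]]
    list(pips = pips,
         report = crossvalidatePanel(Z, y, panel, cfg$folds, cfg,
                                     seed = cvSeedFor(i)))
  }

  if (strategy == "II") {
    fsTime0 <- proc.time()[["elapsed"]]
    pips <- featureSelect(Z, y, cfg, seed = fsSeedFor(1L))
    fsTime <- proc.time()[["elapsed"]] - fsTime0
    panels <- buildPanels(pips, sizes)
    reports <- lapply(seq_len(nPanels), function(i)
      crossvalidatePanel(Z, y, panels[[i]], cfg$folds, cfg,
                         seed = cvSeedFor(i)))
    pipsList <- list(pips)
    fsSeeds <- rep(fsSeedFor(1L), nPanels)
  } else {
    jobs <- if (strategy == "I")
      poolApply(lapply(seq_len(nPanels), function(i) {
        force(i); function() metaJob(i)
      }), cfg$workers)
    else lapply(seq_len(nPanels), metaJob) # strategy III: in series
    pipsList <- lapply(jobs, `[[`, "pips")
    reports <- lapply(jobs, `[[`, "report")
    fsSeeds <- vapply(seq_len(nPanels), fsSeedFor, integer(1))
    fsTime <- NA_real_
  }

  report <- new("PipelineReport", strategy = strategy, pips = pipsList,
                reports = reports, panelSizes = sizes,
                fsSeeds = as.integer(fsSeeds), optimalSize = 0L,
                timings = c(total = proc.time()[["elapsed"]] - t0,
                            fs = if (strategy == "II") fsTime else NA_real_))
  report@optimalSize <- selectOptimal(report)
  report
}

#' Select the optimal panel size from a pipeline report
#'
#' The panel maximizing mean predictive accuracy; ties go to the smaller
#' panel.
#'
#' @param report A [PipelineReport-class].
#' @return Integer panel size.
#' @export
selectOptimal <- function(report) {
  stopifnot(is(report, "PipelineReport"))
  acc <- vapply(report@reports, function(r) r@meanPred, numeric(1))
  if (all(is.na(acc))) stop("all panels have undefined predictive accuracy")
  ord <- order(report@panelSizes)
  sizes <- report@panelSizes[ord]
  acc <- acc[ord]
  sizes[which.max(acc)] # which.max takes the first (= smallest) maximum
}
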