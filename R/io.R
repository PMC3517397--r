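## Readers and writers for the plain-text formats used by the tool:
## additive-coded genotype tables (CSV or PLINK-RAW-style), phenotype CSVs
## keyed by individual id, tidy draw/summary/PIP/CV TSVs, and the YAML run
## configuration. Draw values are written with 17 significant digits so a
## write/read round trip is bit-exact.

fmtNum <- function(x) sprintf("%.17g", x)

#' Read a genotype matrix
#'
#' Two dialects are supported. `"csv"`: a header of SNP ids preceded by an
#' id column, one row per individual. `"plinkraw"`: a whitespace table
#' with the six leading columns FID IID PAT MAT SEX PHENOTYPE followed by
#' per-SNP allele counts (the IID column provides individual ids). Codes
#' must be 0, 1, 2 or missing (NA); missing codes are an error unless
#' `imputeMissing = TRUE`, in which case they are replaced by the column
#' mean of the observed codes (the count of imputed cells is reported via
#' a message).
#'
#' @param path File path.
#' @param format `"csv"` or `"plinkraw"`.
#' @param imputeMissing Impute missing codes by column means.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("csv", "plinkraw"),
                          imputeMissing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- unique(utils::count.fields(path,
                                   sep = if (format == "csv") "," else ""))
  if (length(nf) != 1L) stop("ragged rows in ", path)
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    g <- df[, -1, drop = FALSE]
  } else {
    df <- read.table(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(df) < 6 || !identical(toupper(names(df)[1:6]), lead))
      stop("not a PLINK-RAW-style table: expected leading columns ",
           paste(lead, collapse = " "))
    ids <- as.character(df[["IID"]])
    g <- df[, -(1:6), drop = FALSE]
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
  if (anyDuplicated(names(g))) stop("duplicate SNP ids in ", path)
  gm <- as.matrix(g)
  if (is.character(gm)) {
    bad <- suppressWarnings(is.na(as.numeric(gm)) & !is.na(gm) &
                              gm != "NA")
    if (any(bad)) stop("non-numeric genotype codes in ", path)
    gm <- suppressWarnings(matrix(as.numeric(gm), nrow(gm), ncol(gm),
                                  dimnames = dimnames(gm)))
  }
  ok <- is.na(gm) | gm %in% c(0, 1, 2)
  if (!all(ok))
    stop("invalid genotype codes (must be 0/1/2/NA): e.g. ",
         gm[which(!ok)[1]])
  if (anyNA(gm)) {
    if (!imputeMissing)
      stop(sum(is.na(gm)), " missing genotype codes in ", path,
           "; rerun with imputeMissing = TRUE to use column means")
    nMiss <- sum(is.na(gm))
    for (j in seq_len(ncol(gm))) {
      miss <- is.na(gm[, j])
      if (any(miss)) {
        obs <- gm[!miss, j]
        if (!length(obs)) stop("SNP ", colnames(gm)[j], " is all-missing")
        gm[miss, j] <- mean(obs)
      }
    }
    message("imputed ", nMiss, " missing genotype codes by column means")
  }
  rownames(gm) <- ids
  storage.mode(gm) <- "double"
  new("GenotypeMatrix", geno = gm)
}

#' Write a genotype matrix
#'
#' @param Z A [GenotypeMatrix-class].
#' @param path Output path.
#' @param format `"csv"` or `"plinkraw"`.
#' @return Invisibly, `path`.
#' @export
writeGenotypes <- function(Z, path, format = c("csv", "plinkraw")) {
  format <- match.arg(format)
  g <- genotypes(Z)
  if (format == "csv") {
    df <- data.frame(id = indIds(Z), g, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(FID = indIds(Z), IID = indIds(Z), PAT = 0, MAT = 0,
                     SEX = 0, PHENOTYPE = -9, g, check.names = FALSE)
    write.table(df, path, row.names = FALSE, quote = FALSE, sep = " ")
  }
  invisible(path)
}

#' Read phenotypes aligned to a genotype matrix
#'
#' CSV with header `id,value`. Rows are aligned to the genotype
#' individual order; every genotyped individual must appear exactly once
#' and no extra ids are allowed.
#'
#' @param path File path.
#' @param Z A [GenotypeMatrix-class] giving the target id order.
#' @return Named numeric vector in `indIds(Z)` order.
#' @export
readPhenotypes <- function(path, Z) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected columns id,value in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate phenotype ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(vals)) stop("non-numeric phenotype values in ", path)
  want <- indIds(Z)
  missing <- setdiff(want, ids)
  if (length(missing))
    stop("phenotypes missing for ids: ", paste(missing, collapse = ", "))
  extra <- setdiff(ids, want)
  if (length(extra))
    stop("phenotype rows without genotypes: ",
         paste(extra, collapse = ", "))
  setNames(vals[match(want, ids)], want)
}

#' Read and validate a YAML run configuration
#'
#' Recognized sections/keys: `mcmc` (iters, burnin, thin, chains, seed,
#' workers), `hyper` (nu_alpha, S2_alpha, nu_e, S2_e, pi_fixed),
#' `pipeline` (panel_sizes, folds, strategy, fs_chains), `io` (genotypes,
#' phenotypes, format, outdir). Unknown keys are errors, and the values
#' are checked against the module preconditions before any computation.
#'
#' @param path YAML file path.
#' @return Validated nested list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  schema <- list(
    mcmc = c("iters", "burnin", "thin", "chains", "seed", "workers"),
    hyper = c("nu_alpha", "S2_alpha", "nu_e", "S2_e", "pi_fixed"),
    pipeline = c("panel_sizes", "folds", "strategy", "fs_chains"),
    io = c("genotypes", "phenotypes", "format", "outdir"))
  badSec <- setdiff(names(cfg), names(schema))
  if (length(badSec))
    stop("unknown config section(s): ", paste(badSec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  m <- cfg$mcmc
  if (!is.null(m$iters) && !is.null(m$burnin) && m$burnin >= m$iters)
    stop("config: burnin must be smaller than iters")
  if (!is.null(m$thin) && m$thin < 1) stop("config: thin must be >= 1")
  if (!is.null(cfg$hyper$pi_fixed) &&
      (cfg$hyper$pi_fixed < 0 || cfg$hyper$pi_fixed > 1))
    stop("config: pi_fixed must lie in [0, 1]")
  if (!is.null(cfg$pipeline$folds) && cfg$pipeline$folds < 2)
    stop("config: folds must be >= 2")
  if (!is.null(cfg$pipeline$strategy) &&
      !cfg$pipeline$strategy %in% c("I", "II", "III"))
    stop("config: strategy must be one of I, II, III")
  cfg
}

## ---- report writers -----------------------------------------------------

writeSummaryTable <- function(result, outdir, prefix = "posterior") {
  pooled <- poolChains(result)
  files <- character(0)
  for (par in parameterNames(result)) {
    rows <- lapply(result@chains, function(ch)
      summarizeDraws(ch@draws[, par]))
    tab <- do.call(rbind, rows)
    tab <- rbind(tab, summarizeDraws(pooled[, par]))
    out <- data.frame(sample_set = c(seq_along(result@chains), "Pooled"),
                      Min = fmtNum(tab[, "min"]), Q1 = fmtNum(tab[, "q1"]),
                      Median = fmtNum(tab[, "median"]),
                      Mean = fmtNum(tab[, "mean"]),
                      Q3 = fmtNum(tab[, "q3"]), Max = fmtNum(tab[, "max"]))
    f <- file.path(outdir, paste0(prefix, "_summary_", par, ".tsv"))
    write.table(out, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  files
}

writeDrawsTidy <- function(result, path) {
  rows <- lapply(result@chains, function(ch) {
    d <- ch@draws
    data.frame(chain = ch@chainId,
               iteration = rep(seq_len(nrow(d)), times = ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = fmtNum(as.vector(d)))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  path
}

#' Read tidy draws back into a MultiChainResult
#'
#' Inverse of the tidy draws TSV written by [writeReports()]; values
#' round-trip bit-exactly.
#'
#' @param path Tidy TSV with columns chain, iteration, parameter, value.
#' @return A [MultiChainResult-class].
#' @export
readDraws <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("chain", "iteration", "parameter", "value") %in%
                  names(df)))
  pars <- unique(df$parameter)
  mats <- lapply(sort(unique(df$chain)), function(ci) {
    sub <- df[df$chain == ci, ]
    iters <- sort(unique(sub$iteration))
    m <- matrix(NA_real_, length(iters), length(pars),
                dimnames = list(NULL, pars))
    for (p in pars)
      m[, p] <- sub$value[sub$parameter == p][order(
        sub$iteration[sub$parameter == p])]
    m
  })
  multiChainFromMatrices(mats)
}

writeRunLog <- function(outdir, info) {
  f <- file.path(outdir, "run_log.txt")
  lines <- c(sprintf("package_version: %s",
                     as.character(utils::packageVersion("parMCMCgp"))),
             sprintf("r_version: %s", R.version.string),
             vapply(names(info), function(k)
               sprintf("%s: %s", k, paste(info[[k]], collapse = " ")),
               character(1)))
  writeLines(lines, f)
  f
}

#' @describeIn writeReports Per-parameter six-number summary tables
#'   (per-chain rows plus a Pooled row), a tidy draws TSV, and a run log.
#' @param info Named list of extra fields for the run log (seeds,
#'   partition counts, ...).
setMethod("writeReports", "MultiChainResult",
  function(object, outdir, info = list(), ...) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
    ch <- object@chains[[1]]
    info <- c(list(chains = length(object@chains), burnin = ch@burnin,
                   thin = ch@thin, seed = ch@seed), info)
    files <- c(writeSummaryTable(object, outdir),
               writeDrawsTidy(object, file.path(outdir, "draws.tsv")),
               writeRunLog(outdir, info))
    invisible(files)
  })

#' @describeIn writeReports Additionally writes the PIP table
#'   (snp_id, pip, rank).
setMethod("writeReports", "BayesCResult",
  function(object, outdir, info = list(), ...) {
    files <- writeReports(object@chains, outdir, info = info)
    f <- file.path(outdir, "pip.tsv")
    tab <- pipTable(pip(object))
    tab$pip <- fmtNum(tab$pip)
    write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(c(files, f))
  })

#' @describeIn writeReports Writes the per-panel cross-validation table
#'   and the feature-selection PIP table(s).
setMethod("writeReports", "PipelineReport",
  function(object, outdir, ...) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    cv <- do.call(rbind, lapply(seq_along(object@reports), function(i) {
      r <- object@reports[[i]]
      data.frame(panel_size = r@panelSize, fold = seq_along(r@fitCor),
                 fit_cor = fmtNum(r@fitCor), pred_cor = fmtNum(r@predCor),
                 mean_fit = fmtNum(r@meanFit),
                 mean_pred = fmtNum(r@meanPred),
                 fs_seed = object@fsSeeds[i])
    }))
    f1 <- file.path(outdir, "cv_report.tsv")
    write.table(cv, f1, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- f1
    for (i in seq_along(object@pips)) {
      tab <- object@pips[[i]]
      tab$pip <- fmtNum(tab$pip)
      f <- file.path(outdir, sprintf("pip_fs%d.tsv", i))
      write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    files <- c(files, writeRunLog(outdir, list(
      strategy = object@strategy, optimal_size = object@optimalSize,
      panel_sizes = object@panelSizes)))
    invisible(files)
  })
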