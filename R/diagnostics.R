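## Convergence diagnostics and the burn-in-limited speedup laws for
## multi-chain parallelism.

chainVectors <- function(result, parameter) {
  stopifnot(is(result, "MultiChainResult"))
  if (!parameter %in% parameterNames(result))
    stop(sprintf("parameter '%s' is not monitored", parameter))
  lapply(result@chains, function(ch) ch@draws[, parameter])
}

#' Gelman-Rubin shrink factor (potential scale reduction factor)
#'
#' For `m` chains of `n` retained draws each: `B = n * var(chain means)`,
#' `W = mean(within-chain variances)`, `varplus = (n - 1) * W / n + B / n`,
#' and the shrink factor is `sqrt(varplus / W)`. Values near 1 indicate
#' that within-sequence variance dominates between-sequence variance, i.e.
#' the chains have escaped their starting points. With `corrected = TRUE`
#' the sampling-variability and degrees-of-freedom adjusted variant is
#' computed instead (the form returned by coda's point estimate), used
#' here for cross-checks.
#'
#' @param result A [MultiChainResult-class] with >= 2 chains of >= 2 draws.
#' @param parameter Name of the monitored parameter.
#' @param corrected Apply the d.f. correction (default `FALSE`: the classic
#'   `sqrt(varplus / W)`).
#' @return Scalar shrink factor. If all chains are constant the factor is
#'   1; if within-chain variance is zero but chains differ, `Inf`.
#' @examples
#' r <- multiChainFromMatrices(list(cbind(x = c(1, 2, 3)),
#'                                  cbind(x = c(2, 3, 4))))
#' gelmanRubin(r, "x")  # sqrt(7/6)
#' @export
gelmanRubin <- function(result, parameter, corrected = FALSE) {
  xs <- chainVectors(result, parameter)
  m <- length(xs)
  n <- length(xs[[1]])
  if (m < 2) stop("at least two chains are required")
  if (n < 2) stop("at least two draws per chain are required")
  means <- vapply(xs, mean, numeric(1))
  s2 <- vapply(xs, var, numeric(1))
  W <- mean(s2)
  B <- n * var(means)
  if (W == 0) return(if (B > 0) Inf else 1.0)
  varplus <- (n - 1) * W / n + B / n
  if (!corrected) return(sqrt(varplus / W))
  ## Sampling-variability + d.f. adjusted variant (Gelman & Rubin 1992 /
  ## Brooks & Gelman 1998), as implemented in standard MCMC toolkits.
  V <- varplus + B / (m * n)
  varV <- ((n - 1) / n)^2 / m * var(s2) +
    ((m + 1) / (m * n))^2 * 2 / (m - 1) * B^2 +
    2 * (m + 1) * (n - 1) / (m * n^2) * n / m *
      (cov(s2, means^2) - 2 * mean(means) * cov(s2, means))
  d <- 2 * V^2 / varV
  sqrt((d + 3) / (d + 1) * V / W)
}

#' Shrink-factor series over iteration checkpoints
#'
#' Applies [gelmanRubin()] to the prefix of the retained draws up to each
#' checkpoint, giving the trace used to judge how much burn-in a sampler
#' needs.
#'
#' @inheritParams gelmanRubin
#' @param checkpoints Increasing iteration counts, each <= retained draws
#'   per chain; checkpoints < 2 are skipped with a warning.
#' @return Data frame with columns `checkpoint` and `rhat`.
#' @export
psrfSeries <- function(result, parameter, checkpoints, corrected = FALSE) {
  xs <- chainVectors(result, parameter)
  n <- length(xs[[1]])
  checkpoints <- as.integer(checkpoints)
  if (any(checkpoints > n))
    stop("checkpoints exceed the available retained draws")
  keep <- checkpoints >= 2L
  if (any(!keep)) {
    warning("skipping checkpoints < 2 draws")
    checkpoints <- checkpoints[keep]
  }
  if (!length(checkpoints)) stop("no usable checkpoints")
  rhat <- vapply(checkpoints, function(ck) {
    prefix <- multiChainFromMatrices(lapply(xs, function(x)
      matrix(x[seq_len(ck)], ncol = 1,
             dimnames = list(NULL, parameter))))
    gelmanRubin(prefix, parameter, corrected = corrected)
  }, numeric(1))
  data.frame(checkpoint = checkpoints, rhat = rhat)
}

#' Suggest a burn-in from a shrink-factor series
#'
#' The smallest checkpoint at which the shrink factor has dropped to the
#' threshold or below.
#'
#' @param series Data frame from [psrfSeries()].
#' @param threshold Convergence threshold, > 1 (default 1.1).
#' @return The checkpoint (integer), or `NA_integer_` if the series never
#'   crosses the threshold ("not converged").
#' @export
suggestBurnin <- function(series, threshold = 1.1) {
  stopifnot(is.data.frame(series), nrow(series) >= 1, threshold > 1)
  ok <- which(series$rhat <= threshold)
  if (!length(ok)) return(NA_integer_)
  as.integer(series$checkpoint[min(ok)])
}

#' Multi-chain speedup law, burn-in fraction form
#'
#' If a fraction `rho` of the post-burn-in length `n` must be spent in
#' burn-in by every chain, running `K` chains in parallel gives speedup
#' `S = (rho * n + n) / (rho * n + n / K)`, bounded above by
#' `1 + 1 / rho` as `K` grows.
#'
#' @param rho Burn-in fraction in (0, 1].
#' @param n Post-burn-in iterations, > 0.
#' @param K Number of parallel chains/workers (vectorized).
#' @return Numeric speedup(s).
#' @seealso [speedupFractionLimit()], [speedupBurnin()]
#' @export
speedupFraction <- function(rho, n, K) {
  stopifnot(rho > 0, rho <= 1, n > 0, all(K >= 1))
  (rho * n + n) / (rho * n + n / K)
}

#' @rdname speedupFraction
#' @return `speedupFractionLimit(rho)`: the large-`K` asymptote
#'   `1 + 1 / rho`.
#' @export
speedupFractionLimit <- function(rho) {
  stopifnot(rho > 0, rho <= 1)
  1 + 1 / rho
}

#' Multi-chain speedup law, burn-in count form
#'
#' With `b` burn-in iterations and `n` post-burn-in iterations, `K`
#' parallel chains (each running `b + n/K` iterations) give speedup
#' `S = (b + n) / (b + n / K)`; with `b = 0` the speedup is exactly
#' `K`-fold ("perfectly parallel"), and for `b > 0` it is bounded above by
#' `1 + n / b`.
#'
#' @param b Burn-in iterations, >= 0.
#' @param n Post-burn-in iterations, >= 1.
#' @param K Number of parallel chains (vectorized).
#' @return Numeric speedup(s).
#' @examples
#' speedupBurnin(1, 10, 8)   # about 5
#' speedupBurninLimit(1, 10) # 11
#' @export
speedupBurnin <- function(b, n, K) {
  stopifnot(b >= 0, n >= 1, all(K >= 1))
  (b + n) / (b + n / K)
}

#' @rdname speedupBurnin
#' @return `speedupBurninLimit(b, n)`: the large-`K` asymptote `1 + n / b`
#'   (`Inf` when `b = 0`).
#' @export
speedupBurninLimit <- function(b, n) {
  stopifnot(b >= 0, n >= 1)
  if (b == 0) return(Inf)
  1 + n / b
}

#' Assemble a MultiChainResult from plain draw matrices
#'
#' Convenience constructor (used by the diagnostics and the draw readers):
#' wraps equally-shaped named draw matrices as chains 1, 2, ...
#'
#' @param mats List of draw matrices with identical column names and row
#'   counts.
#' @param burnin,thin,seed Metadata to record on each chain.
#' @return A [MultiChainResult-class].
#' @export
multiChainFromMatrices <- function(mats, burnin = 0L, thin = 1L,
                                   seed = 0L) {
  chains <- lapply(seq_along(mats), function(i) {
    m <- as.matrix(mats[[i]])
    if (is.null(colnames(m)))
      colnames(m) <- paste0("par_", seq_len(ncol(m)))
    new("ChainSamples", draws = m, burnin = as.integer(burnin),
        thin = as.integer(thin), seed = as.integer(seed),
        chainId = as.integer(i))
  })
  new("MultiChainResult", chains = chains)
}
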