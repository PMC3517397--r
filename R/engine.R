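## Master/worker execution. The "parallel substrate" is an in-process
## worker pool (forked via parallel::mclapply when workers > 1). Because
## every unit of work owns an RNG stream keyed by its identity (worker id,
## chain id or block id) and reductions run in ascending index order, the
## output is a pure function of (model, size, seed) and is bit-identical
## across reruns and worker counts.

#' Partition a workload across workers
#'
#' Unweighted partitions differ by at most one unit; weighted partitions
#' are floor-rounded proportional shares with the residual assigned to the
#' lowest-index workers. The counts always sum exactly to `total`.
#'
#' @param total Total number of work units, >= 0.
#' @param K Number of workers, >= 1.
#' @param weights Optional positive weights of length `K` (e.g. relative
#'   worker speeds).
#' @return Integer vector of length `K` of per-worker counts.
#' @examples
#' partitionWork(7, 3)            # 3 2 2
#' partitionWork(100, 2, c(3, 1)) # 75 25
#' @export
partitionWork <- function(total, K, weights = NULL) {
  stopifnot(length(total) == 1L, total >= 0, total == as.integer(total))
  if (length(K) != 1L || K < 1 || K != as.integer(K))
    stop("'K' must be a positive integer")
  K <- as.integer(K)
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K) stop("'weights' must have length K")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("'weights' must be positive")
  shares <- total * weights / sum(weights)
  counts <- as.integer(floor(shares))
  residual <- as.integer(total) - sum(counts)
  if (residual > 0)
    counts[seq_len(residual)] <- counts[seq_len(residual)] + 1L
  stopifnot(sum(counts) == total)
  counts
}

## Schedule one task per worker; abort (naming the worker) on any failure.
## Results come back in ascending worker index regardless of scheduling.
poolApply <- function(tasks, workers) {
  run <- function(j) tryCatch(list(ok = TRUE, value = tasks[[j]]()),
                              error = function(e)
                                list(ok = FALSE, msg = conditionMessage(e)))
  ids <- seq_along(tasks)
  res <- if (workers > 1L)
    parallel::mclapply(ids, run, mc.cores = workers, mc.preschedule = TRUE)
  else lapply(ids, run)
  for (j in ids) {
    r <- res[[j]]
    if (!is.list(r) || !isTRUE(r$ok))
      stop(sprintf("worker %d failed: %s", j,
                   if (is.list(r)) r$msg else as.character(r)))
  }
  lapply(res, `[[`, "value")
}

#' Parallel Monte Carlo estimation
#'
#' Master/worker Monte Carlo: the workload of `total` draws is partitioned
#' over `K` streams; worker `j` draws its portion under the RNG stream
#' `(baseSeed, j)` and returns its partial sum; the master reduces partial
#' sums in ascending worker index and forms the pooled estimate
#' `sum(S_j) / total`. Reruns with the same `(baseSeed, K)` are
#' bit-identical, whatever `workers` is used for scheduling.
#'
#' @param sampler Function of one argument `m` returning `m` draws, pure in
#'   the current RNG state (e.g. `function(m) rposterior(post, m)`).
#' @param total Total number of draws.
#' @param K Number of portions/streams.
#' @param baseSeed Integer base seed.
#' @param weights Optional worker weights, see [partitionWork()].
#' @param workers Scheduling parallelism for the worker pool (does not
#'   affect the result).
#' @return List with `estimate` (pooled mean), `summary` (six-number
#'   summary of the pooled draws, see [summarizeDraws()]), `draws` (pooled,
#'   concatenated in worker order), `partition`, `workerSums` and
#'   `workerMeans`.
#' @examples
#' post <- posteriorMeanKnownVariance(4, 1, 3.394, 0.58, 7670)
#' mc <- parallelMonteCarlo(function(m) rposterior(post, m), 1e4, 10, 7)
#' mc$estimate
#' @export
parallelMonteCarlo <- function(sampler, total, K, baseSeed, weights = NULL,
                               workers = 1L) {
  stopifnot(is.function(sampler))
  part <- partitionWork(total, K, weights)
  tasks <- lapply(seq_len(K), function(j) {
    force(j)
    function() withStream(baseSeed, j, {
      draws <- sampler(part[j])
      if (length(draws) != part[j])
        stop(sprintf("sampler returned %d draws, expected %d",
                     length(draws), part[j]))
      list(draws = draws, S = sum(draws))
    })
  })
  res <- poolApply(tasks, workers)
  workerSums <- vapply(res, `[[`, numeric(1), "S")
  draws <- unlist(lapply(res, `[[`, "draws"), use.names = FALSE)
  estimate <- sum(workerSums) / total
  list(estimate = estimate, summary = summarizeDraws(draws), draws = draws,
       partition = part, workerSums = workerSums,
       workerMeans = workerSums / pmax(part, 1L))
}

checkKernel <- function(model) {
  need <- c("init", "step", "monitor")
  if (!is.list(model) || !all(need %in% names(model)) ||
      !all(vapply(model[need], is.function, logical(1))))
    stop("'model' must be a list with functions init(), step(state), ",
         "monitor(state)")
}

#' Run multiple independent MCMC chains
#'
#' Chain `i` is initialized (over-dispersed, via `model$init()`) and run
#' entirely under the RNG stream `(baseSeed, i)`; chains are whole
#' scheduling units (a worker may own several chains, a chain is never
#' split). The result is independent of `workers`.
#'
#' @param model MCMC kernel contract: a list with `init()` returning a
#'   state, `step(state)` returning the next state, and `monitor(state)`
#'   returning a named numeric vector of monitored values.
#' @param chains Number of chains, >= 1.
#' @param iters Iterations per chain.
#' @param burnin Iterations to discard (must be < `iters`).
#' @param thin Thinning interval (retain every `thin`-th post-burn-in
#'   iteration).
#' @param baseSeed Integer base seed.
#' @param workers Scheduling parallelism.
#' @return A [MultiChainResult-class].
#' @export
runMultiChain <- function(model, chains, iters, burnin = 0L, thin = 1L,
                          baseSeed = 1L, workers = 1L) {
  checkKernel(model)
  stopifnot(chains >= 1, iters >= 1, thin >= 1)
  if (burnin >= iters) stop("'burnin' must be smaller than 'iters'")
  keep <- floor((iters - burnin) / thin)
  if (keep < 1) stop("no retained draws: increase 'iters' or lower 'thin'")
  tasks <- lapply(seq_len(chains), function(i) {
    force(i)
    function() withStream(baseSeed, i, {
      state <- model$init()
      probe <- model$monitor(state)
      out <- matrix(NA_real_, keep, length(probe),
                    dimnames = list(NULL, names(probe)))
      r <- 0L
      for (t in seq_len(iters)) {
        state <- model$step(state)
        if (t > burnin && (t - burnin) %% thin == 0L) {
          r <- r + 1L
          out[r, ] <- model$monitor(state)
        }
      }
      new("ChainSamples", draws = out, burnin = as.integer(burnin),
          thin = as.integer(thin), seed = as.integer(baseSeed),
          chainId = as.integer(i))
    })
  })
  new("MultiChainResult", chains = poolApply(tasks, workers))
}

#' Pool retained draws across chains
#'
#' Concatenates per-chain draw matrices in chain-id order after discarding
#' an optional number of additional leading rows per chain.
#'
#' @param result A [MultiChainResult-class].
#' @param extraBurnin Additional retained rows to drop from the start of
#'   every chain (must leave at least one row).
#' @return Matrix of pooled draws.
#' @export
poolChains <- function(result, extraBurnin = 0L) {
  stopifnot(is(result, "MultiChainResult"))
  validObject(result)
  nr <- nrow(result@chains[[1]]@draws)
  if (extraBurnin < 0 || extraBurnin >= nr)
    stop("'extraBurnin' must be in [0, retained draws per chain)")
  do.call(rbind, lapply(result@chains, function(ch)
    ch@draws[(extraBurnin + 1L):nr, , drop = FALSE]))
}

#' Parallel Gibbs updates within a single chain
#'
#' For models that split into a (cheap) scale update and many location
#' updates that are conditionally independent given the scale and the
#' data, one chain can be parallelized: each iteration, the master samples
#' the scale, then the location blocks are updated concurrently. Each block
#' owns a persistent RNG stream keyed by its block id (`(seed, b)`; the
#' master owns stream 0), so the sampled trajectory is bit-identical for
#' any worker count — the operational meaning of preserving the target
#' posterior under parallelization.
#'
#' @param model Block-update contract: a list with `nBlocks`,
#'   `conditionallyIndependent = TRUE`, `init()`, `updateScale(state)`,
#'   `updateBlock(state, b)` returning the new value of block `b`,
#'   `setBlock(state, b, value)` merging it, and `monitor(state)`. Models
#'   that do not declare conditional independence are refused.
#' @param workers Number of workers blocks are scheduled over.
#' @param iters Number of iterations.
#' @param seed Integer base seed.
#' @param burnin,thin Retention controls as in [runMultiChain()].
#' @return A [ChainSamples-class].
#' @seealso [groupMeansModel()] for a ready-made kernel.
#' @export
withinChainParallelUpdate <- function(model, workers, iters, seed,
                                      burnin = 0L, thin = 1L) {
  need <- c("init", "updateScale", "updateBlock", "setBlock", "monitor")
  if (!is.list(model) || !all(need %in% names(model)))
    stop("'model' must provide ", paste(need, collapse = ", "))
  if (!isTRUE(model$conditionallyIndependent))
    stop("model does not declare conditional independence of its location ",
         "blocks; within-chain parallel updating is refused")
  q <- as.integer(model$nBlocks)
  stopifnot(q >= 1, iters >= 1, thin >= 1)
  if (burnin >= iters) stop("'burnin' must be smaller than 'iters'")
  keep <- floor((iters - burnin) / thin)

  masterState <- rngStream(seed, 0L)
  blockStates <- lapply(seq_len(q), function(b) rngStream(seed, b))
  init <- withRNGState(masterState, model$init(), capture = TRUE)
  state <- init$value
  masterState <- init$state
  part <- partitionWork(q, max(1L, as.integer(workers)))
  probe <- model$monitor(state)
  out <- matrix(NA_real_, keep, length(probe),
                dimnames = list(NULL, names(probe)))
  r <- 0L
  for (t in seq_len(iters)) {
    sc <- withRNGState(masterState, model$updateScale(state), capture = TRUE)
    state <- sc$value
    masterState <- sc$state
    ## block updates: scheduled over workers, merged in ascending block id;
    ## per-block streams make the schedule immaterial
    for (b in seq_len(q)) {
      up <- withRNGState(blockStates[[b]], model$updateBlock(state, b),
                         capture = TRUE)
      blockStates[[b]] <- up$state
      state <- model$setBlock(state, b, up$value)
    }
    if (t > burnin && (t - burnin) %% thin == 0L) {
      r <- r + 1L
      out[r, ] <- model$monitor(state)
    }
  }
  new("ChainSamples", draws = out, burnin = as.integer(burnin),
      thin = as.integer(thin), seed = as.integer(seed), chainId = 1L)
}

#' Gibbs kernel for the one-way group-means model
#'
#' The demonstration model for within-chain parallelism: observations
#' `y_ij ~ N(theta_i, sigma2_e)` with group means `theta_i ~ N(0,
#' sigma2_theta)` (known prior variance) and a scaled inverse-chi-squared
#' prior on `sigma2_e`. Given `sigma2_e` and the data, the `theta_i` are
#' conditionally independent, so each is a location block.
#'
#' @param data List with numeric `y` and integer `group` (as produced by
#'   [simulateGroupMeans()]).
#' @param sigmaTheta2 Known prior variance of the group means.
#' @param nuE,S2E Prior degrees of freedom and scale for `sigma2_e`.
#' @param sigmaE2Fixed Optional value at which to hold `sigma2_e` fixed
#'   (the scale update is then a no-op).
#' @return A kernel list for [withinChainParallelUpdate()].
#' @export
groupMeansModel <- function(data, sigmaTheta2, nuE = 4, S2E = 1,
                            sigmaE2Fixed = NULL) {
  stopifnot(is.numeric(data$y), length(data$y) == length(data$group),
            sigmaTheta2 > 0)
  y <- data$y
  g <- as.integer(data$group)
  q <- max(g)
  ng <- tabulate(g, q)
  if (any(ng == 0)) stop("empty groups are not allowed")
  sumg <- vapply(seq_len(q), function(b) sum(y[g == b]), numeric(1))
  N <- length(y)
  list(
    nBlocks = q,
    conditionallyIndependent = TRUE,
    init = function() {
      s2e <- if (is.null(sigmaE2Fixed))
        nuE * S2E / rchisq(1, nuE) else sigmaE2Fixed
      list(theta = rnorm(q, 0, 2 * sqrt(sigmaTheta2)), sigma2e = s2e)
    },
    updateScale = function(state) {
      if (is.null(sigmaE2Fixed)) {
        sse <- sum((y - state$theta[g])^2)
        state$sigma2e <- (sse + nuE * S2E) / rchisq(1, nuE + N)
      }
      state
    },
    updateBlock = function(state, b) {
      prec <- ng[b] / state$sigma2e + 1 / sigmaTheta2
      rnorm(1, (sumg[b] / state$sigma2e) / prec, sqrt(1 / prec))
    },
    setBlock = function(state, b, value) {
      state$theta[b] <- value
      state
    },
    monitor = function(state) {
      c(sigma2_e = state$sigma2e,
        setNames(state$theta, paste0("theta_", seq_len(q))))
    })
}
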