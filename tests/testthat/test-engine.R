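# Master/worker engine: partitioning, reduction, stream discipline.

test_that("work partitions are exact and near-equal (or weight-proportional)", {
  expect_equal(partitionWork(1e6, 10), rep(1e5, 10))
  expect_equal(partitionWork(7, 3), c(3L, 2L, 2L))
  expect_equal(partitionWork(100, 2, c(3, 1)), c(75L, 25L))
  expect_error(partitionWork(10, 0), "positive integer")
  expect_error(partitionWork(10, 2, c(1, -1)), "positive")
  for (s in 1:20) {
    tot <- s * 13 + 1
    K <- (s %% 7) + 1
    part <- partitionWork(tot, K)
    expect_equal(sum(part), tot)
    expect_lte(diff(range(part)), 1L)
  }
  # weighted partitions still sum exactly
  part <- partitionWork(101, 3, c(0.2, 0.5, 0.3))
  expect_equal(sum(part), 101L)
})

test_that("parallel Monte Carlo pools partial sums reproducibly", {
  # constant sampler: estimate is exactly the constant
  mc <- parallelMonteCarlo(function(m) rep(2.5, m), 1000, 4, 1)
  expect_identical(mc$estimate, 2.5)

  # CLT bound for a standard normal sampler
  mc <- parallelMonteCarlo(function(m) rnorm(m), 1e5, 4, 123)
  expect_lt(abs(mc$estimate), 4 / sqrt(1e5))

  # bit-identical rerun, and invariance to the scheduling worker count
  again <- parallelMonteCarlo(function(m) rnorm(m), 1e5, 4, 123)
  expect_identical(mc$draws, again$draws)
  sched <- parallelMonteCarlo(function(m) rnorm(m), 1e5, 4, 123,
                              workers = 3)
  expect_identical(mc$draws, sched$draws)

  # pooled mean equals the partition-weighted mean of worker means
  expect_equal(mc$estimate,
               sum(mc$workerMeans * mc$partition) / sum(mc$partition),
               tolerance = 1e-12)

  # a failing worker aborts the run and is named
  expect_error(
    parallelMonteCarlo(function(m) if (m == 3) stop("boom") else rnorm(m),
                       10, 3, 1),
    "worker 2 failed")
})

simpleKernel <- function(post) {
  list(init = function() list(x = rnorm(1, 0, 10)),
       step = function(state) list(x = rposterior(post, 1)),
       monitor = function(state) c(x = state$x))
}

test_that("multi-chain runs are seeded per chain and bit-reproducible", {
  post <- posteriorMeanKnownVariance(0, 1, 2, 1, 50)
  res <- runMultiChain(simpleKernel(post), chains = 10, iters = 300,
                       burnin = 50, thin = 1, baseSeed = 5)
  expect_s4_class(res, "MultiChainResult")
  expect_equal(nChains(res), 10)
  expect_equal(nrow(chainDraws(res)[[1]]), 250)

  # pooled mean within 4 SE of the conjugate oracle
  pooled <- poolChains(res)
  expect_lt(abs(mean(pooled[, "x"]) - posteriorMean(post)),
            4 * sqrt(posteriorVariance(post) / nrow(pooled)))

  # K = 1 reduces to a serial run on the same stream
  one <- runMultiChain(simpleKernel(post), chains = 1, iters = 300,
                       burnin = 50, baseSeed = 5)
  expect_identical(chainDraws(one)[[1]], chainDraws(res)[[1]])

  # rerun and worker-count invariance are bit-exact
  again <- runMultiChain(simpleKernel(post), chains = 10, iters = 300,
                         burnin = 50, baseSeed = 5, workers = 4)
  expect_identical(chainDraws(res), chainDraws(again))

  expect_error(runMultiChain(simpleKernel(post), chains = 2, iters = 100,
                             burnin = 100, baseSeed = 1), "burnin")
})

test_that("pooling concatenates chains in id order with extra burn-in", {
  mats <- list(cbind(x = 1:100 / 1), cbind(x = 1:100 + 1000))
  res <- multiChainFromMatrices(mats)
  expect_equal(nrow(poolChains(res)), 200)
  expect_equal(nrow(poolChains(res, 50)), 100)
  expect_equal(poolChains(res)[1:100, "x"], as.numeric(1:100))
  expect_error(poolChains(res, 100), "extraBurnin")

  same <- multiChainFromMatrices(list(cbind(x = sin(1:50)),
                                      cbind(x = sin(1:50))))
  expect_equal(mean(poolChains(same)[, "x"]), mean(sin(1:50)))
})

test_that("within-chain parallel Gibbs is invariant to the worker count", {
  dat <- simulateGroupMeans(20, 30, 1, 0.5, seed = 5)
  model <- groupMeansModel(dat, sigmaTheta2 = 1)
  c1 <- withinChainParallelUpdate(model, workers = 1, iters = 200, seed = 9)
  c4 <- withinChainParallelUpdate(model, workers = 4, iters = 200, seed = 9)
  expect_identical(chainDraws(c1), chainDraws(c4))

  # refuse models that do not declare conditional independence
  bad <- model
  bad$conditionallyIndependent <- FALSE
  expect_error(withinChainParallelUpdate(bad, 2, 10, 1), "refused")
})

test_that("group-means posterior means match their conjugate oracles", {
  q <- 50
  npg <- 40
  s2e <- 0.5
  s2t <- 1
  dat <- simulateGroupMeans(q, npg, s2t, s2e, seed = 21)
  # fixed residual variance: each theta_i draw is an exact conjugate
  # normal, so draws are iid across iterations
  model <- groupMeansModel(dat, sigmaTheta2 = s2t, sigmaE2Fixed = s2e)
  ch <- withinChainParallelUpdate(model, workers = 2, iters = 2000,
                                  seed = 31, burnin = 100)
  d <- chainDraws(ch)
  for (b in c(1, 7, 25, 50)) {
    sumb <- sum(dat$y[dat$group == b])
    prec <- npg / s2e + 1 / s2t
    oracleMean <- (sumb / s2e) / prec
    x <- d[, paste0("theta_", b)]
    expect_lt(abs(mean(x) - oracleMean),
              4 * sqrt(1 / prec / length(x)))
  }
})

test_that("a single location block reduces to two-block Gibbs", {
  dat <- simulateGroupMeans(1, 50, 1, 0.5, seed = 2)
  model <- groupMeansModel(dat, sigmaTheta2 = 1)
  ch <- withinChainParallelUpdate(model, workers = 1, iters = 500, seed = 3,
                                  burnin = 100)
  expect_equal(colnames(chainDraws(ch)), c("sigma2_e", "theta_1"))
  # posterior of theta_1 concentrates near the sample mean
  expect_lt(abs(mean(chainDraws(ch)[, "theta_1"]) - mean(dat$y)), 0.3)
})

test_that("stream addressing is scheduling-independent and restores state", {
  s1 <- withStream(42, 1, rnorm(5))
  s2 <- withStream(42, 2, rnorm(5))
  expect_false(isTRUE(all.equal(s1, s2)))
  expect_identical(s1, withStream(42, 1, rnorm(5)))
  # caller RNG state is untouched
  set.seed(1)
  before <- .Random.seed
  invisible(withStream(9, 3, rnorm(10)))
  expect_identical(before, .Random.seed)
})
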