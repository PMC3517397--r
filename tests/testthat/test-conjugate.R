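# Closed-form conjugate posteriors and their sampling behaviour.

test_that("precision-weighted posterior of a normal mean matches hand values", {
  post <- posteriorMeanKnownVariance(4.0, 1.0, 3.394, 0.58, 7670)
  expect_equal(round(posteriorMean(post), 3), 3.394)
  # high-precision evaluation of 1/(1 + 7670/0.58), frozen from an
  # independent arbitrary-precision computation
  expect_equal(posteriorVariance(post), 7.5613578112737e-05,
               tolerance = 1e-12)

  # no data returns the prior
  prior <- posteriorMeanKnownVariance(4.0, 1.0, 3.394, 0.58, 0)
  expect_equal(posteriorMean(prior), 4.0)
  expect_equal(posteriorVariance(prior), 1.0)

  # equal precisions average symmetrically
  eq <- posteriorMeanKnownVariance(0, 1, 1, 1, 1)
  expect_equal(posteriorMean(eq), 0.5)
  expect_equal(posteriorVariance(eq), 0.5)

  expect_error(posteriorMeanKnownVariance(0, 0, 1, 1, 1), "tau02")
  expect_error(posteriorMeanKnownVariance(0, 1, 1, -2, 1), "sigma2")

  # interpreting the stated spread as an SD to be squared changes the fit
  alt <- posteriorMeanKnownVariance(4.0, 1.0, 3.394, 0.58, 7670,
                                    sdSquared = TRUE)
  expect_false(isTRUE(all.equal(posteriorVariance(alt),
                                posteriorVariance(post))))
})

test_that("flat-prior limit of the mean posterior recovers (ybar, sigma2/n)", {
  post <- posteriorMeanKnownVariance(100, 1e12, 3.394, 0.58, 7670)
  expect_equal(posteriorMean(post), 3.394, tolerance = 1e-6)
  expect_equal(posteriorVariance(post), 0.58 / 7670, tolerance = 1e-6)
})

test_that("variance posterior with known mean matches hand evaluation", {
  post <- posteriorVarianceKnownMean(2, 1, 2, 2)
  expect_equal(post@df, 4)
  expect_equal(post@scale, 1.5)
  expect_equal(posteriorMean(post), 3.0)

  # n = 0 returns the prior unchanged
  prior <- posteriorVarianceKnownMean(5, 2.5, 99, 0)
  expect_equal(prior@df, 5)
  expect_equal(prior@scale, 2.5)

  # data dominate the prior
  dom <- posteriorVarianceKnownMean(4, 1, 1, 100)
  expect_equal(posteriorMean(dom), 1, tolerance = 0.05)

  # df <= 2: distribution valid, expectation flagged undefined
  small <- posteriorVarianceKnownMean(1, 1, 1, 1)
  expect_warning(m <- posteriorMean(small), "undefined")
  expect_true(is.na(m))

  # Monte Carlo cross-check: sampled median vs analytic median
  draws <- withStream(7, 0, rposterior(post, 2e5))
  expect_equal(median(draws), post@df * post@scale / qchisq(0.5, post@df),
               tolerance = 0.02)
})

test_that("two-parameter marginals are inverse-chi-squared and Student-t", {
  m <- twoParamMarginals(c(1, 2, 3))
  expect_equal(m$sigma2@df, 2)
  expect_equal(m$sigma2@scale, 1)
  expect_equal(m$mu@df, 2)
  expect_equal(m$mu@center, 2.0)
  expect_equal(m$mu@scale2, 1 / 3)

  expect_error(twoParamMarginals(c(5, 5, 5)), "degenerate")
  expect_error(twoParamMarginals(3), "two observations")

  # scaling the data scales the variance marginal by c^2, the center by c
  y <- withStream(3, 0, rnorm(50, 2, 1.5))
  a <- twoParamMarginals(y)
  b <- twoParamMarginals(7 * y)
  expect_equal(b$sigma2@scale, 49 * a$sigma2@scale)
  expect_equal(b$mu@center, 7 * a$mu@center)
  expect_equal(b$sigma2@df, a$sigma2@df)

  # large-sample behaviour
  big <- twoParamMarginals(withStream(4, 0, rnorm(1e4, 5, 2)))
  expect_lt(abs(big$mu@center - 5), 0.1)
})

test_that("six-number summaries follow the Min/Q1/Median/Mean/Q3/Max layout", {
  expect_equal(unname(summarizeDraws(1:5)), c(1, 2, 3, 3, 4, 5))
  expect_equal(unname(summarizeDraws(rep(2.5, 10))), rep(2.5, 6))
  expect_error(summarizeDraws(numeric(0)), "empty")
  # ordering invariant on arbitrary draws
  for (s in 1:5) {
    x <- withStream(s, 0, rcauchy(100))
    sm <- summarizeDraws(x)
    expect_true(sm["min"] <= sm["q1"] && sm["q1"] <= sm["median"] &&
                  sm["median"] <= sm["q3"] && sm["q3"] <= sm["max"])
  }
})

test_that("sampling each closed-form posterior reproduces its analytic moments", {
  n <- 1e6
  np <- posteriorMeanKnownVariance(4, 1, 3.394, 0.58, 7670)
  d <- withStream(11, 0, rposterior(np, n))
  expect_lt(abs(mean(d) - posteriorMean(np)),
            4 * sqrt(posteriorVariance(np) / n))
  expect_equal(unname(quantile(d, c(0.25, 0.75))),
               quantile(np, c(0.25, 0.75)), tolerance = 1e-4)

  sic <- new("ScaledInvChi2", df = 10, scale = 2)
  d <- withStream(12, 0, rposterior(sic, n))
  expect_lt(abs(mean(d) - posteriorMean(sic)),
            4 * sqrt(posteriorVariance(sic) / n))

  st <- new("StudentTPosterior", df = 10, center = -1, scale2 = 0.5)
  d <- withStream(13, 0, rposterior(st, n))
  expect_lt(abs(mean(d) - posteriorMean(st)),
            4 * sqrt(posteriorVariance(st) / n))
})
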