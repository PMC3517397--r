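## Closed-form conjugate posteriors for the normal model. These are exact
## and double as oracles for the Monte Carlo / MCMC machinery.

#' Posterior of a normal mean with known variance
#'
#' Combines a `Normal(mu0, tau02)` prior with `n` observations of known
#' variance `sigma2` and sample mean `ybar`. The posterior is normal with
#' mean the precision-weighted average of prior mean and sample mean,
#' `(mu0/tau02 + n*ybar/sigma2) / (1/tau02 + n/sigma2)`, and variance
#' `1 / (1/tau02 + n/sigma2)`.
#'
#' @param mu0 Prior mean (trait units).
#' @param tau02 Prior variance, > 0.
#' @param ybar Sample mean.
#' @param sigma2 Known data variance, > 0. If `sdSquared = TRUE` the value
#'   is interpreted as a standard deviation and squared first.
#' @param n Number of observations, >= 0 (`n = 0` returns the prior).
#' @param sdSquared Interpret `sigma2` as an SD to be squared. Default
#'   `FALSE`: the stated population variance is used as a variance, which
#'   for the cattle daily-gain example reproduces the published posterior
#'   quartiles.
#' @return A [NormalPosterior-class].
#' @examples
#' posteriorMeanKnownVariance(4.0, 1.0, 3.394, 0.58, 7670)
#' @export
posteriorMeanKnownVariance <- function(mu0, tau02, ybar, sigma2, n,
                                       sdSquared = FALSE) {
  stopifnot(is.finite(mu0), is.finite(ybar), n >= 0, n == as.integer(n))
  if (!is.finite(tau02) || tau02 <= 0)
    stop("prior variance 'tau02' must be positive")
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("data variance 'sigma2' must be positive")
  if (sdSquared) sigma2 <- sigma2^2
  prec <- 1 / tau02 + n / sigma2
  new("NormalPosterior",
      mean = (mu0 / tau02 + n * ybar / sigma2) / prec,
      variance = 1 / prec)
}

#' Posterior of a normal variance with known mean
#'
#' With a scaled inverse-chi-squared prior `(nu0, s02)` and sufficient
#' statistic `S2` (mean squared deviation from the known mean) of `n`
#' observations, the posterior is scaled inverse-chi-squared with
#' `df = nu0 + n` and `scale = (nu0*s02 + n*S2) / (nu0 + n)`.
#'
#' @param nu0 Prior degrees of freedom, > 0.
#' @param s02 Prior scale, > 0.
#' @param S2 Mean squared deviation of the data about the known mean, >= 0.
#' @param n Number of observations, >= 0 (`n = 0` returns the prior).
#' @return A [ScaledInvChi2-class]. Its expectation is only defined when
#'   `df > 2` (see [posteriorMean()]).
#' @examples
#' posteriorVarianceKnownMean(2, 1, 2, 2)  # df 4, scale 1.5, mean 3
#' @export
posteriorVarianceKnownMean <- function(nu0, s02, S2, n) {
  if (!is.finite(nu0) || nu0 <= 0) stop("prior df 'nu0' must be positive")
  if (!is.finite(s02) || s02 <= 0) stop("prior scale 's02' must be positive")
  stopifnot(n >= 0, n == as.integer(n))
  if (n > 0 && (!is.finite(S2) || S2 < 0))
    stop("sufficient statistic 'S2' must be >= 0")
  if (n == 0) return(new("ScaledInvChi2", df = nu0, scale = s02))
  new("ScaledInvChi2", df = nu0 + n,
      scale = (nu0 * s02 + n * S2) / (nu0 + n))
}

#' Marginal posteriors of a normal mean and variance (both unknown)
#'
#' Under the vague joint prior proportional to `1/sigma2`, the marginal
#' posterior of the variance is scaled inverse-chi-squared with `n - 1`
#' degrees of freedom and scale `s2` (the sample variance), and the
#' marginal posterior of the mean is Student-t with `n - 1` degrees of
#' freedom, center `ybar` and squared scale `s2 / n`.
#'
#' @param y Numeric data vector, length >= 2, not constant.
#' @return List with components `sigma2` ([ScaledInvChi2-class]) and
#'   `mu` ([StudentTPosterior-class]).
#' @examples
#' twoParamMarginals(c(1, 2, 3))
#' @export
twoParamMarginals <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("'y' must be finite numeric")
  n <- length(y)
  if (n < 2) stop("at least two observations are required")
  s2 <- var(y)
  if (s2 == 0) stop("degenerate scale: 'y' is constant")
  list(sigma2 = new("ScaledInvChi2", df = n - 1, scale = s2),
       mu = new("StudentTPosterior", df = n - 1, center = mean(y),
                scale2 = s2 / n))
}

#' Six-number summary of posterior draws
#'
#' Min, first quartile, median, mean, third quartile, max — the layout used
#' for per-chain posterior summary tables. Quartiles use linear
#' interpolation between order statistics (R's default quantile type 7).
#'
#' @param draws Non-empty numeric vector of draws.
#' @return Named numeric vector `c(min, q1, median, mean, q3, max)`.
#' @examples
#' summarizeDraws(1:5)
#' @export
summarizeDraws <- function(draws) {
  if (!length(draws)) stop("empty draws")
  if (!is.numeric(draws) || any(!is.finite(draws)))
    stop("draws must be finite numeric")
  q <- unname(quantile(draws, c(0.25, 0.5, 0.75), type = 7))
  c(min = min(draws), q1 = q[1], median = q[2], mean = mean(draws),
    q3 = q[3], max = max(draws))
}

## ---- distribution methods ----------------------------------------------

#' @describeIn rposterior Normal draws.
setMethod("rposterior", "NormalPosterior", function(object, n) {
  rnorm(n, object@mean, sqrt(object@variance))
})

#' @describeIn rposterior Scaled inverse-chi-squared draws
#'   (`df * scale / rchisq(n, df)`).
setMethod("rposterior", "ScaledInvChi2", function(object, n) {
  object@df * object@scale / rchisq(n, object@df)
})

#' @describeIn rposterior Location-scale Student-t draws.
setMethod("rposterior", "StudentTPosterior", function(object, n) {
  object@center + sqrt(object@scale2) * rt(n, object@df)
})

#' @describeIn posteriorMean The posterior mean itself.
setMethod("posteriorMean", "NormalPosterior", function(object) object@mean)

#' @describeIn posteriorMean `df * scale / (df - 2)`; `NA` with a warning
#'   when `df <= 2`.
setMethod("posteriorMean", "ScaledInvChi2", function(object) {
  if (object@df <= 2) {
    warning("expectation undefined: df <= 2")
    return(NA_real_)
  }
  object@df * object@scale / (object@df - 2)
})

#' @describeIn posteriorMean The center (df > 1 assumed for existence).
setMethod("posteriorMean", "StudentTPosterior", function(object) {
  if (object@df <= 1) {
    warning("expectation undefined: df <= 1")
    return(NA_real_)
  }
  object@center
})

#' @describeIn posteriorVariance The posterior variance itself.
setMethod("posteriorVariance", "NormalPosterior",
          function(object) object@variance)

#' @describeIn posteriorVariance `2 df^2 scale^2 / ((df-2)^2 (df-4))` for
#'   `df > 4`, else `NA`.
setMethod("posteriorVariance", "ScaledInvChi2", function(object) {
  if (object@df <= 4) {
    warning("variance undefined: df <= 4")
    return(NA_real_)
  }
  2 * object@df^2 * object@scale^2 /
    ((object@df - 2)^2 * (object@df - 4))
})

#' @describeIn posteriorVariance `scale2 * df / (df - 2)` for `df > 2`,
#'   else `NA`.
setMethod("posteriorVariance", "StudentTPosterior", function(object) {
  if (object@df <= 2) {
    warning("variance undefined: df <= 2")
    return(NA_real_)
  }
  object@scale2 * object@df / (object@df - 2)
})

#' Quantiles of a closed-form posterior
#'
#' @param x A [NormalPosterior-class] or [StudentTPosterior-class].
#' @param probs Probabilities.
#' @param ... Ignored.
#' @return Numeric vector of quantiles.
#' @export
setMethod("quantile", "NormalPosterior", function(x, probs = c(0.25, 0.75), ...) {
  qnorm(probs, x@mean, sqrt(x@variance))
})

#' @rdname quantile-NormalPosterior-method
#' @export
setMethod("quantile", "StudentTPosterior", function(x, probs = c(0.25, 0.75), ...) {
  x@center + sqrt(x@scale2) * qt(probs, x@df)
})
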