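#' Weibull time-to-event parameters in rate form
#'
#' All time-to-event distributions in the model use the rate
#' parametrization \eqn{F(t) = 1 - e^{-\lambda t^k}} with shape \eqn{k}
#' and scale (rate) \eqn{\lambda}. With \eqn{k = 1} this is the
#' exponential distribution. Note this differs from the
#' scale parametrization used by [stats::pweibull()]; the two are related
#' by \eqn{\lambda = b^{-k}} for `pweibull` scale \eqn{b}.
#'
#' @param shape shape parameter k, strictly positive.
#' @param scale rate parameter lambda, strictly positive.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale), length(shape) == 1L,
            length(scale) == 1L)
  if (!is.finite(shape) || shape <= 0) {
    stop("weibull shape must be strictly positive", call. = FALSE)
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("weibull scale must be strictly positive", call. = FALSE)
  }
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' Cumulative distribution function of the rate-form Weibull
#'
#' @param params a [weibull_params()] object.
#' @param t event time in years, `t >= 0` (vectorized).
#' @return \eqn{F(t) = 1 - e^{-\lambda t^k}}, in `[0, 1)`.
#' @export
weibull_cdf <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  -expm1(-params$scale * t^params$shape)
}

#' Quantile (inverse CDF) of the rate-form Weibull
#'
#' @param params a [weibull_params()] object.
#' @param p probability in `[0, 1)` (vectorized).
#' @return Time t such that `weibull_cdf(params, t) = p`.
#' @export
weibull_quantile <- function(params, p) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)", call. = FALSE)
  (-log1p(-p) / params$scale)^(1 / params$shape)
}

#' Calibrate a Weibull scale to a cumulative probability at a horizon
#'
#' Given the probability of an event within `horizon` years and a fixed
#' shape, solves \eqn{\lambda = -\ln(1 - p) / T^k} so that the fitted CDF
#' reproduces the probability exactly at the horizon. This is how every
#' ten-year outcome probability and five-year post-event mortality in the
#' base-case configuration is turned into a sampling distribution.
#'
#' @param p_horizon cumulative event probability at the horizon, in (0, 1).
#' @param horizon horizon in years, positive.
#' @param shape Weibull shape k (default 1, exponential).
#' @return A [weibull_params()] object.
#' @export
calibrate_scale <- function(p_horizon, horizon, shape = 1) {
  stopifnot(is.numeric(p_horizon), length(p_horizon) == 1L)
  if (!is.finite(p_horizon) || p_horizon <= 0 || p_horizon >= 1) {
    stop("p_horizon must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  weibull_params(shape = shape, scale = -log1p(-p_horizon) / horizon^shape)
}

#' Fit a Weibull through two cumulative-probability anchor points
#'
#' Solves shape and scale so that the CDF passes through `(t1, p1)` and
#' `(t2, p2)` exactly:
#' \eqn{k = \ln(\ln(1-p2)/\ln(1-p1)) / \ln(t2/t1)},
#' \eqn{\lambda = -\ln(1-p1)/t1^k}. Used to turn reported 1-year and
#' 5-year post-event mortality into a full survival distribution.
#'
#' @param t1,t2 anchor times in years, `0 < t1 < t2`.
#' @param p1,p2 cumulative probabilities at the anchors, `0 < p1 < p2 < 1`.
#' @return A [weibull_params()] object reproducing both anchors.
#' @export
fit_weibull_two_points <- function(t1, p1, t2, p2) {
  if (!(t1 > 0 && t2 > t1)) {
    stop("anchor times must satisfy 0 < t1 < t2", call. = FALSE)
  }
  if (!(p1 > 0 && p2 > p1 && p2 < 1)) {
    stop("anchor probabilities must satisfy 0 < p1 < p2 < 1", call. = FALSE)
  }
  k <- log(log1p(-p2) / log1p(-p1)) / log(t2 / t1)
  weibull_params(shape = k, scale = -log1p(-p1) / t1^k)
}

#' Rescale an event time under a proportional change of the Weibull scale
#'
#' A treatment risk ratio enters the model as a multiplier on the Weibull
#' scale, \eqn{\lambda' = rr \cdot \lambda}. Holding the underlying
#' uniform draw fixed (common random numbers), the sampled time transforms
#' as \eqn{t' = t \cdot rr^{-1/k}}: an `rr < 1` pushes events later.
#'
#' @param t sampled event time(s), positive.
#' @param rr risk ratio (scale multiplier), positive.
#' @param shape Weibull shape k of the distribution `t` was drawn from.
#' @return Rescaled time(s).
#' @export
rescale_event_time <- function(t, rr, shape) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  if (!is.finite(rr) || rr <= 0) stop("rr must be positive", call. = FALSE)
  t * rr^(-1 / shape)
}

# inverse-CDF sampling from a vector of uniforms
sample_weibull_times <- function(u, scale, shape) {
  (-log1p(-u) / scale)^(1 / shape)
}
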