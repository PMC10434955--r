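#' The amplified sine-Weibull distribution
#'
#' The sine-G family with Weibull baseline
#' \eqn{G(t) = 1 - e^{-\alpha t^\delta}}. All functions are exact closed-form
#' compositions of the family transform with the Weibull baseline; the
#' survival of the baseline \eqn{e^{-\alpha t^\delta}} is carried exactly so
#' the upper tail keeps full floating-point precision.
#'
#' The quantile function is closed form,
#' \deqn{t_q = \left(-\frac{1}{\alpha}\log\left[1 - \frac{2}{\pi}
#'   \sin^{-1}\!\left(\frac{\lambda q}{\lambda - 1 + q}\right)\right]\right)^{1/\delta}.}
#'
#' @param x,q vector of quantiles, >= 0.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param delta Weibull shape, > 0.
#' @param alpha Weibull rate-scale (units \eqn{time^{-\delta}}), > 0.
#' @param lambda amplification parameter, > 1.
#' @param log,log.p,lower.tail as in \code{\link{pnts}}.
#' @return \code{dntsw} density, \code{pntsw} distribution function,
#'   \code{qntsw} quantiles, \code{rntsw} random deviates.
#' @examples
#' pntsw(1, delta = 2.5, alpha = 2.2, lambda = 1.5)
#' qntsw(0.5, delta = 0.42771, alpha = 0.88512, lambda = 1.02405)
#' @name ntsw
NULL

check_ntsw <- function(delta, alpha, lambda) {
  stopifnot(is.finite(delta), delta > 0, is.finite(alpha), alpha > 0)
  check_lambda(lambda)
}

#' @rdname ntsw
#' @export
pntsw <- function(q, delta, alpha, lambda, lower.tail = TRUE, log.p = FALSE) {
  check_ntsw(delta, alpha, lambda)
  if (any(!is.finite(q)) || any(q < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  SG <- exp(-alpha * q^delta)
  s <- sin(pi / 2 * (1 - SG))
  oms <- 2 * sin(pi / 4 * SG)^2
  den <- (lambda - 1) + oms
  val <- if (lower.tail) s * (lambda - 1) / den else lambda * oms / den
  val <- pmin(pmax(val, 0), 1)
  if (log.p) log(val) else val
}

#' @rdname ntsw
#' @export
dntsw <- function(x, delta, alpha, lambda, log = FALSE) {
  check_ntsw(delta, alpha, lambda)
  if (any(!is.finite(x)) || any(x < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  SG <- exp(-alpha * x^delta)
  oms <- 2 * sin(pi / 4 * SG)^2
  den <- (lambda - 1) + oms
  ld <- log(pi) + log(lambda) + log(lambda - 1) +
    log(alpha) + log(delta) + (delta - 1) * log(x) - alpha * x^delta +
    log(sin(pi / 2 * SG)) - log(2) - 2 * log(den)
  if (log) ld else exp(ld)
}

#' @rdname ntsw
#' @export
qntsw <- function(p, delta, alpha, lambda) {
  check_ntsw(delta, alpha, lambda)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  arg <- lambda * p / (lambda - 1 + p)
  (-log1p(-2 / pi * asin(pmin(arg, 1))) / alpha)^(1 / delta)
}

#' @rdname ntsw
#' @export
rntsw <- function(n, delta, alpha, lambda) {
  stopifnot(n >= 1)
  u <- stats::runif(n)
  qntsw(pmin(pmax(u, 1e-12), 1 - 1e-12), delta, alpha, lambda)
}

#' Survival, hazard and cumulative hazard of the sine-Weibull member
#'
#' @inheritParams ntsw
#' @return numeric vector.
#' @export
sntsw <- function(x, delta, alpha, lambda) {
  pntsw(x, delta, alpha, lambda, lower.tail = FALSE)
}

#' @rdname sntsw
#' @export
hntsw <- function(x, delta, alpha, lambda) {
  s <- sntsw(x, delta, alpha, lambda)
  f <- dntsw(x, delta, alpha, lambda)
  ifelse(s > 0, f / s, Inf)
}

#' @rdname sntsw
#' @export
chntsw <- function(x, delta, alpha, lambda) {
  -pntsw(x, delta, alpha, lambda, lower.tail = FALSE, log.p = TRUE)
}

# ---------------------------------------------------------------------------
# Competitor lifetime models used in the model comparison.
#
# Parameter conventions (all parameters > 0):
#   weibull          delta, alpha           S = exp(-alpha t^delta)
#   exp-weibull      delta, alpha, tau      F = (1 - exp(-alpha t^delta))^tau
#   sine-weibull     delta, alpha           F = sin[(pi/2)(1 - exp(-alpha t^delta))]
#   sine-inv-weibull delta, alpha           F = sin[(pi/2) exp(-alpha t^-delta)]
#   napc-weibull     delta, alpha, alpha1   S = (a1 - a1^sin[(pi/2)G])/(a1 - 1),
#                                           G Weibull CDF, alpha1 != 1
#
# The sine-inverse-Weibull uses the inverse-Weibull baseline
# exp(-alpha t^-delta): this is the only reading under which the survival
# function is valid (decreasing from 1 to 0).
# ---------------------------------------------------------------------------

competitor_models <- c("weibull", "exp-weibull", "sine-weibull",
                       "sine-inv-weibull", "napc-weibull")

competitor_cdf <- function(t, model, params) {
  p <- params
  switch(model,
    "weibull" = -expm1(-p[["alpha"]] * t^p[["delta"]]),
    "exp-weibull" = (-expm1(-p[["alpha"]] * t^p[["delta"]]))^p[["tau"]],
    "sine-weibull" = sin(pi / 2 * (-expm1(-p[["alpha"]] * t^p[["delta"]]))),
    "sine-inv-weibull" = sin(pi / 2 * exp(-p[["alpha"]] * t^(-p[["delta"]]))),
    "napc-weibull" = {
      a1 <- p[["alpha1"]]
      if (a1 == 1) stop("napc-weibull requires alpha1 != 1", call. = FALSE)
      G <- -expm1(-p[["alpha"]] * t^p[["delta"]])
      (a1^sin(pi / 2 * G) - 1) / (a1 - 1)
    },
    stop("unknown competitor model: ", model, call. = FALSE)
  )
}

competitor_lpdf <- function(t, model, params) {
  p <- params
  lw <- function() log(p[["alpha"]]) + log(p[["delta"]]) +
    (p[["delta"]] - 1) * log(t) - p[["alpha"]] * t^p[["delta"]]
  switch(model,
    "weibull" = lw(),
    "exp-weibull" = {
      G <- -expm1(-p[["alpha"]] * t^p[["delta"]])
      log(p[["tau"]]) + (p[["tau"]] - 1) * log(G) + lw()
    },
    "sine-weibull" = {
      G <- -expm1(-p[["alpha"]] * t^p[["delta"]])
      log(pi / 2) + log(cos(pi / 2 * G)) + lw()
    },
    "sine-inv-weibull" = {
      E <- exp(-p[["alpha"]] * t^(-p[["delta"]]))
      log(pi / 2) + log(cos(pi / 2 * E)) - p[["alpha"]] * t^(-p[["delta"]]) +
        log(p[["alpha"]]) + log(p[["delta"]]) - (p[["delta"]] + 1) * log(t)
    },
    "napc-weibull" = {
      a1 <- p[["alpha1"]]
      if (a1 == 1) stop("napc-weibull requires alpha1 != 1", call. = FALSE)
      G <- -expm1(-p[["alpha"]] * t^p[["delta"]])
      log(abs(log(a1))) + sin(pi / 2 * G) * log(a1) - log(abs(a1 - 1)) +
        log(pi / 2) + log(cos(pi / 2 * G)) + lw()
    },
    stop("unknown competitor model: ", model, call. = FALSE)
  )
}

#' Survival functions of the competitor lifetime models
#'
#' The five classical competitors used alongside the amplified sine-Weibull
#' in model comparison: Weibull, exponentiated Weibull, sine-Weibull,
#' sine-inverse-Weibull and the new-alpha-power-cosine Weibull. See the
#' package vignette for the exact parameterizations.
#'
#' @param t times, >= 0.
#' @param model one of \code{"weibull"}, \code{"exp-weibull"},
#'   \code{"sine-weibull"}, \code{"sine-inv-weibull"}, \code{"napc-weibull"}.
#' @param params named numeric vector of parameters (see Details in the
#'   source registry: \code{delta}, \code{alpha}, plus \code{tau} for the
#'   exponentiated Weibull and \code{alpha1} for the alpha-power-cosine
#'   model).
#' @return survival probabilities in [0, 1].
#' @examples
#' competitor_sf(1, "weibull", c(delta = 1.05357, alpha = 0.09165))
#' @export
competitor_sf <- function(t, model, params) {
  model <- match.arg(model, competitor_models)
  stopifnot(all(t >= 0), all(params > 0))
  pmin(pmax(1 - competitor_cdf(t, model, params), 0), 1)
}
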