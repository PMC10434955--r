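#' Baseline distribution specification
#'
#' The sine-G transform acts on an arbitrary continuous baseline distribution
#' \eqn{G(t;\kappa)}. A baseline is specified by its CDF, PDF and quantile
#' function together with a named parameter vector and per-parameter box
#' bounds. The three functions must take \code{(x, kappa)} where \code{kappa}
#' is the named numeric vector.
#'
#' @param name identifier for the baseline (e.g. \code{"weibull"}).
#' @param cdf function \code{(x, kappa)} returning \eqn{G(x)}.
#' @param pdf function \code{(x, kappa)} returning \eqn{g(x) \ge 0}.
#' @param quantile function \code{(p, kappa)} returning \eqn{G^{-1}(p)}.
#' @param kappa named numeric vector of baseline parameters.
#' @param lower,upper named numeric vectors of parameter bounds (same names
#'   as \code{kappa}).
#' @param support numeric length-2 vector, support of the baseline.
#' @return An object of class \code{"nts_baseline"}.
#' @examples
#' b <- baseline_weibull(delta = 2, alpha = 1)
#' b$cdf(1, b$kappa)
#' @export
nts_baseline <- function(name, cdf, pdf, quantile, kappa,
                         lower = NULL, upper = NULL,
                         support = c(0, Inf)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(cdf), is.function(pdf), is.function(quantile),
            is.numeric(kappa), !is.null(names(kappa)))
  if (is.null(lower)) lower <- stats::setNames(rep(1e-8, length(kappa)), names(kappa))
  if (is.null(upper)) upper <- stats::setNames(rep(1e3, length(kappa)), names(kappa))
  structure(list(name = name, cdf = cdf, pdf = pdf, quantile = quantile,
                 kappa = kappa, lower = lower, upper = upper,
                 support = support),
            class = "nts_baseline")
}

#' Weibull baseline \eqn{G(t) = 1 - \exp(-\alpha t^\delta)}
#'
#' Rate-scale parameterization: \code{alpha} has units \eqn{time^{-\delta}}.
#' This differs from \code{\link[stats]{pweibull}}'s scale \eqn{b} by
#' \eqn{\alpha = b^{-\delta}}.
#'
#' @param delta shape, > 0.
#' @param alpha rate-scale, > 0.
#' @return An \code{"nts_baseline"} object.
#' @export
baseline_weibull <- function(delta, alpha) {
  stopifnot(delta > 0, alpha > 0)
  nts_baseline(
    name = "weibull",
    cdf = function(x, kappa) {
      ifelse(x <= 0, 0, -expm1(-kappa[["alpha"]] * x^kappa[["delta"]]))
    },
    pdf = function(x, kappa) {
      ifelse(x <= 0, 0,
             kappa[["alpha"]] * kappa[["delta"]] * x^(kappa[["delta"]] - 1) *
               exp(-kappa[["alpha"]] * x^kappa[["delta"]]))
    },
    quantile = function(p, kappa) {
      (-log1p(-p) / kappa[["alpha"]])^(1 / kappa[["delta"]])
    },
    kappa = c(delta = delta, alpha = alpha),
    lower = c(delta = 1e-3, alpha = 1e-8),
    upper = c(delta = 50, alpha = 1e3)
  )
}

#' Exponential baseline \eqn{G(t) = 1 - \exp(-rate\, t)}
#'
#' @param rate rate parameter, > 0.
#' @return An \code{"nts_baseline"} object.
#' @export
baseline_exponential <- function(rate = 1) {
  stopifnot(rate > 0)
  nts_baseline(
    name = "exponential",
    cdf = function(x, kappa) ifelse(x <= 0, 0, -expm1(-kappa[["rate"]] * x)),
    pdf = function(x, kappa) ifelse(x <= 0, 0, kappa[["rate"]] * exp(-kappa[["rate"]] * x)),
    quantile = function(p, kappa) -log1p(-p) / kappa[["rate"]],
    kappa = c(rate = rate),
    lower = c(rate = 1e-8), upper = c(rate = 1e3)
  )
}

# internal: validate the amplification parameter. The family degenerates at
# lambda = 1 (CDF identically 0), so lambda must stay strictly above 1.
check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda))
    stop("`lambda` must be a single finite number", call. = FALSE)
  if (lambda < 1 + 1e-6)
    stop("`lambda` must be > 1 (the family is degenerate at lambda = 1); ",
         "need lambda >= 1 + 1e-6", call. = FALSE)
  invisible(lambda)
}

check_baseline <- function(baseline) {
  if (!inherits(baseline, "nts_baseline"))
    stop("`baseline` must be an `nts_baseline` object", call. = FALSE)
  invisible(baseline)
}
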