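#' Goodness-of-fit statistics for a fitted lifetime CDF
#'
#' Classical EDF statistics evaluated at a candidate CDF: the
#' Cramer-von Mises statistic
#' \deqn{W = \sum_{i=1}^n \left[\frac{2i-1}{2n} - G(t_{(i)})\right]^2 + \frac{1}{12n},}
#' the Anderson-Darling statistic
#' \deqn{A = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)\left[\log G(t_{(i)}) +
#'   \log\{1 - G(t_{(n-i+1)})\}\right],}
#' and the two-sided Kolmogorov-Smirnov sup distance
#' \eqn{D = \max_i \max\{i/n - G(t_{(i)}),\; G(t_{(i)}) - (i-1)/n\}.}
#' Data are sorted internally (stable sort; ties kept as-is), so all three
#' are invariant to input ordering. Inside the Anderson-Darling sum the CDF
#' values are clipped to \eqn{[10^{-15}, 1-10^{-15}]} to avoid
#' \code{log(0)}; exact 0/1 values trigger a warning.
#'
#' @param x lifetimes (any order).
#' @param cdf function of one argument returning the fitted CDF, or an
#'   \code{"nts_fit"} object.
#' @return the statistic value.
#' @examples
#' fit <- nts_fit(survival_times(), "weibull")
#' ks_stat(survival_times(), fit)
#' @export
cvm_stat <- function(x, cdf) {
  u <- gof_u(x, cdf)
  n <- length(u)
  i <- seq_len(n)
  sum(((2 * i - 1) / (2 * n) - u)^2) + 1 / (12 * n)
}

#' @rdname cvm_stat
#' @export
ad_stat <- function(x, cdf) {
  u <- gof_u(x, cdf)
  if (any(u <= 0 | u >= 1)) {
    warning("fitted CDF hit 0 or 1 at a data point; clipped to [1e-15, 1-1e-15]")
    u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  }
  n <- length(u)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' @rdname cvm_stat
#' @export
ks_stat <- function(x, cdf) {
  u <- gof_u(x, cdf)
  n <- length(u)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

# internal: sorted fitted-CDF values with validity checks
gof_u <- function(x, cdf) {
  f <- if (inherits(cdf, "nts_fit")) fit_cdf(cdf) else cdf
  stopifnot(is.function(f))
  u <- f(sort(x, method = "radix"))
  if (any(!is.finite(u))) stop("fitted CDF returned non-finite values", call. = FALSE)
  u
}

#' Asymptotic Kolmogorov p-value
#'
#' Tail probability of the Kolmogorov distribution,
#' \eqn{2\sum_{k\ge1}(-1)^{k-1} e^{-2k^2 n D^2}}, truncated once terms fall
#' below 1e-12 and clipped to [0, 1]. No estimated-parameter correction is
#' applied.
#'
#' @param ks KS statistic in (0, 1).
#' @param n sample size.
#' @return p-value in [0, 1].
#' @examples
#' ks_pvalue(0.04926, 128)  # ~0.915
#' @export
ks_pvalue <- function(ks, n) {
  stopifnot(ks >= 0, n >= 1)
  if (ks == 0) return(1)
  tot <- 0
  for (k in 1:1000) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * n * ks^2)
    tot <- tot + term
    if (abs(term) < 1e-12) break
  }
  min(max(2 * tot, 0), 1)
}

#' Goodness-of-fit report for one fitted model
#'
#' @param fit an \code{"nts_fit"} object (or a list with \code{model} and a
#'   CDF via \code{cdf}).
#' @param x optional data; defaults to the data stored in the fit.
#' @return list with \code{model}, \code{cvm}, \code{ad}, \code{ks},
#'   \code{ks_pvalue}.
#' @export
gof_report <- function(fit, x = NULL) {
  if (is.null(x)) x <- fit$data
  list(model = fit$model,
       cvm = cvm_stat(x, fit),
       ad = ad_stat(x, fit),
       ks = ks_stat(x, fit),
       ks_pvalue = ks_pvalue(ks_stat(x, fit), length(x)))
}

#' Fit and compare several lifetime models on one sample
#'
#' Fits every requested model by \code{\link{nts_fit}}, computes the three
#' EDF statistics and the asymptotic KS p-value, and ranks the models by
#' each criterion (rank 1 = best, i.e. smallest statistic or largest
#' p-value). Individual model failures are recorded and the comparison
#' proceeds.
#'
#' @param x positive lifetimes.
#' @param models character vector of model names (>= 2), see
#'   \code{\link{nts_models}}.
#' @param n_starts optional cap on starts per model.
#' @return object of class \code{"nts_model_comparison"}: a data.frame with
#'   one row per model (estimates as a list column \code{fit}).
#' @examples
#' cmp <- compare_models(survival_times(), c("weibull", "sine-weibull"))
#' cmp
#' @export
compare_models <- function(x, models = nts_models(), n_starts = NULL) {
  stopifnot(length(models) >= 2)
  rows <- lapply(models, function(m) {
    fit <- tryCatch(nts_fit(x, m, n_starts = n_starts), error = function(e) NULL)
    if (is.null(fit) || is.null(fit$estimates)) {
      return(data.frame(model = m, loglik = NA_real_, cvm = NA_real_,
                        ad = NA_real_, ks = NA_real_, ks_pvalue = NA_real_,
                        failed = TRUE))
    }
    g <- gof_report(fit, x)
    data.frame(model = m, loglik = fit$loglik, cvm = g$cvm, ad = g$ad,
               ks = g$ks, ks_pvalue = g$ks_pvalue, failed = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank_cvm <- rank(out$cvm, na.last = "keep")
  out$rank_ad <- rank(out$ad, na.last = "keep")
  out$rank_ks <- rank(out$ks, na.last = "keep")
  out$rank_pvalue <- rank(-out$ks_pvalue, na.last = "keep")
  class(out) <- c("nts_model_comparison", "data.frame")
  out
}

#' @export
print.nts_model_comparison <- function(x, digits = 5, ...) {
  cat("Model comparison (n models =", nrow(x), ")\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot-data export for fitted-CDF overlays and PP/QQ point sets
#'
#' Returns (and optionally writes as CSV) the point sets behind the
#' standard fit-diagnostic displays: the empirical and fitted CDF at the
#' order statistics, PP coordinates and QQ coordinates.
#'
#' @param fit an \code{"nts_fit"} object.
#' @param path optional CSV path to write.
#' @return data.frame with columns \code{t}, \code{ecdf}, \code{fitted_cdf},
#'   \code{pp_x}, \code{pp_y}, \code{qq_x}, \code{qq_y}.
#' @export
gof_plot_data <- function(fit, path = NULL) {
  d <- sort(fit$data); n <- length(d)
  u <- fit_cdf(fit)(d)
  pr <- (seq_len(n) - 0.5) / n
  qq_x <- if (fit$model == "nts-weibull") {
    e <- fit$estimates
    qntsw(pr, e[1], e[2], e[3])
  } else {
    reg <- model_registry(fit$model)
    vapply(pr, function(p) stats::uniroot(function(t) reg$cdf(t, fit$estimates) - p,
                                          lower = 1e-12, upper = 1e12,
                                          extendInt = "upX", tol = 1e-9)$root,
           numeric(1))
  }
  out <- data.frame(t = d, ecdf = seq_len(n) / n, fitted_cdf = u,
                    pp_x = pr, pp_y = u, qq_x = qq_x, qq_y = d)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
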