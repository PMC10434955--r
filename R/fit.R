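#' @section Model registry:
#' Internal registry of fittable lifetime models. Each entry carries the
#' parameter names, box bounds, log-density, CDF and a deterministic list of
#' starting points derived from a Weibull moment fit of the data.
#' @noRd
model_registry <- function(model) {
  switch(model,
    "nts-weibull" = list(
      parnames = c("delta", "alpha", "lambda"),
      lower = c(1e-3, 1e-8, 1 + 1e-6),
      upper = c(50, 1e3, 1e4),
      lpdf = function(x, p) dntsw(x, p[[1]], p[[2]], p[[3]], log = TRUE),
      cdf = function(x, p) pntsw(x, p[[1]], p[[2]], p[[3]]),
      starts = function(x) {
        w <- weibull_moment_start(x)
        out <- list()
        for (d in c(w[1], w[1] / 2))
          for (l in c(1.01, 1.1, 1.5, 2))
            out[[length(out) + 1L]] <- c(d, w[2], l)
        out
      }
    ),
    "weibull" = list(
      parnames = c("delta", "alpha"),
      lower = c(1e-3, 1e-8), upper = c(50, 1e3),
      lpdf = function(x, p) competitor_lpdf(x, "weibull", c(delta = p[[1]], alpha = p[[2]])),
      cdf = function(x, p) competitor_cdf(x, "weibull", c(delta = p[[1]], alpha = p[[2]])),
      starts = function(x) {
        w <- weibull_moment_start(x)
        list(w, c(w[1] / 2, w[2]), c(2 * w[1], w[2]), c(1, 1 / mean(x)))
      }
    ),
    "exp-weibull" = list(
      parnames = c("delta", "alpha", "tau"),
      lower = c(1e-3, 1e-8, 1e-3), upper = c(50, 1e3, 1e3),
      lpdf = function(x, p) competitor_lpdf(x, "exp-weibull", c(delta = p[[1]], alpha = p[[2]], tau = p[[3]])),
      cdf = function(x, p) competitor_cdf(x, "exp-weibull", c(delta = p[[1]], alpha = p[[2]], tau = p[[3]])),
      starts = function(x) {
        w <- weibull_moment_start(x)
        list(c(w, 1), c(w[1] / 2, w[2], 5), c(w[1] / 3, 2 * w[2], 15), c(1, 1 / mean(x), 1))
      }
    ),
    "sine-weibull" = list(
      parnames = c("delta", "alpha"),
      lower = c(1e-3, 1e-8), upper = c(50, 1e3),
      lpdf = function(x, p) competitor_lpdf(x, "sine-weibull", c(delta = p[[1]], alpha = p[[2]])),
      cdf = function(x, p) competitor_cdf(x, "sine-weibull", c(delta = p[[1]], alpha = p[[2]])),
      starts = function(x) {
        w <- weibull_moment_start(x)
        list(w, c(w[1] / 2, w[2]), c(1, 1 / mean(x)), c(2 * w[1], w[2]))
      }
    ),
    "sine-inv-weibull" = list(
      parnames = c("delta", "alpha"),
      lower = c(1e-3, 1e-8), upper = c(50, 1e3),
      lpdf = function(x, p) competitor_lpdf(x, "sine-inv-weibull", c(delta = p[[1]], alpha = p[[2]])),
      cdf = function(x, p) competitor_cdf(x, "sine-inv-weibull", c(delta = p[[1]], alpha = p[[2]])),
      starts = function(x) {
        m <- stats::median(x)
        list(c(1, m), c(0.5, 2 * m), c(1.5, m / 2), c(0.7, 3))
      }
    ),
    "napc-weibull" = list(
      parnames = c("delta", "alpha", "alpha1"),
      lower = c(1e-3, 1e-8, 1e-3), upper = c(50, 1e3, 1e3),
      lpdf = function(x, p) competitor_lpdf(x, "napc-weibull", c(delta = p[[1]], alpha = p[[2]], alpha1 = p[[3]])),
      cdf = function(x, p) competitor_cdf(x, "napc-weibull", c(delta = p[[1]], alpha = p[[2]], alpha1 = p[[3]])),
      starts = function(x) {
        w <- weibull_moment_start(x)
        list(c(w, 2), c(w, 8), c(w[1] / 2, w[2], 20), c(1, 1 / mean(x), 2))
      }
    ),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Fittable model names
#' @return character vector of the models accepted by \code{\link{nts_fit}}.
#' @export
nts_models <- function() {
  c("nts-weibull", competitor_models)
}

# Weibull (shape, rate-scale) start by matching mean and coefficient of
# variation: CV^2 = Gamma(1+2/d)/Gamma(1+1/d)^2 - 1, solved for d.
weibull_moment_start <- function(x) {
  cv2 <- stats::var(x) / mean(x)^2
  f <- function(d) expm1(lgamma(1 + 2 / d) - 2 * lgamma(1 + 1 / d)) - cv2
  d <- tryCatch(stats::uniroot(f, c(0.08, 30), tol = 1e-8)$root,
                error = function(e) 1)
  b <- mean(x) / gamma(1 + 1 / d)
  c(d, b^(-d))
}

#' Log-likelihood of a lifetime model
#'
#' Sum of log densities; returns \code{-Inf} (never an error or NaN) when a
#' data point falls outside the support or the parameters are invalid, so
#' numerical optimizers can recover.
#'
#' @param par numeric parameter vector in registry order (see
#'   \code{\link{nts_fit}}), e.g. \code{c(delta, alpha, lambda)} for
#'   \code{"nts-weibull"}.
#' @param x positive lifetimes.
#' @param model model name, see \code{\link{nts_models}}.
#' @return scalar log-likelihood, possibly \code{-Inf}.
#' @export
nts_loglik <- function(par, x, model = "nts-weibull") {
  model <- match.arg(model, nts_models())
  reg <- model_registry(model)
  if (any(par < reg$lower) || any(par > reg$upper)) return(-Inf)
  v <- tryCatch(sum(reg$lpdf(x, par)), error = function(e) -Inf)
  if (!is.finite(v)) -Inf else v
}

#' Maximum-likelihood fit of a lifetime model
#'
#' Box-constrained likelihood maximization by \code{optim(method =
#' "L-BFGS-B")} from multiple deterministic starting points (a Weibull
#' moment fit of the data crossed with a grid of amplification values for
#' the three-parameter model), returning the best optimum found.
#'
#' The amplification parameter \eqn{\lambda} is bounded in
#' \eqn{[1 + 10^{-6}, 10^4]}: the family degenerates at \eqn{\lambda = 1}
#' and approaches the plain sine-G transform as \eqn{\lambda \to \infty}.
#' The likelihood in \eqn{\lambda} is typically very flat (a ridge), so
#' different software can report visibly different \eqn{\lambda} estimates
#' at nearly identical likelihood; see the package vignette.
#'
#' @param x positive lifetimes, length >= 3.
#' @param model model name, one of \code{\link{nts_models}}.
#' @param start optional single numeric start vector (registry order);
#'   overrides the multistart grid. Used e.g. by simulation studies that
#'   start at the data-generating parameters.
#' @param n_starts optional cap on the number of starts taken from the
#'   deterministic grid.
#' @param se logical, compute numerical-Hessian standard errors.
#' @return an object of class \code{"nts_fit"} with components
#'   \code{estimates}, \code{loglik}, \code{converged}, \code{n_starts},
#'   \code{best_start}, \code{se}, \code{model}, \code{data}.
#' @examples
#' x <- survival_times()
#' fit <- nts_fit(x, "weibull")
#' coef(fit); logLik(fit)
#' @export
nts_fit <- function(x, model = "nts-weibull", start = NULL, n_starts = NULL,
                    se = FALSE) {
  model <- match.arg(model, nts_models())
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0))
    stop("`x` must be finite positive lifetimes", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations to fit", call. = FALSE)
  reg <- model_registry(model)
  starts <- if (!is.null(start)) {
    stopifnot(length(start) == length(reg$parnames))
    list(as.numeric(start))
  } else {
    s <- reg$starts(x)
    if (!is.null(n_starts)) s[seq_len(min(n_starts, length(s)))] else s
  }
  nll <- function(p) {
    v <- nts_loglik(p, x, model)
    if (!is.finite(v)) 1e10 else -v
  }
  fits <- lapply(starts, function(s0) {
    s0 <- pmin(pmax(s0, reg$lower), reg$upper)
    tryCatch(
      c(stats::optim(s0, nll, method = "L-BFGS-B",
                     lower = reg$lower, upper = reg$upper),
        list(start = s0)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value) && f$value < 1e9, fits)
  if (length(fits) == 0) {
    return(structure(list(model = model, estimates = NULL, loglik = -Inf,
                          converged = FALSE, n_starts = length(starts),
                          best_start = NULL, se = NULL, data = x,
                          message = "all starts failed"),
                     class = "nts_fit"))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  est <- stats::setNames(best$par, reg$parnames)
  se_vec <- NULL
  if (se) {
    H <- tryCatch(num_hessian(function(p) nts_loglik(p, x, model), best$par),
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0))
        se_vec <- stats::setNames(sqrt(diag(V)), reg$parnames)
    }
  }
  structure(list(model = model, estimates = est, loglik = -best$value,
                 converged = best$convergence == 0,
                 n_starts = length(starts),
                 best_start = stats::setNames(best$start, reg$parnames),
                 se = se_vec, data = x),
            class = "nts_fit")
}

# central-difference Hessian, step 1e-4 * (1 + |theta|)
num_hessian <- function(f, theta) {
  k <- length(theta)
  h <- 1e-4 * (1 + abs(theta))
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- rep(0, k); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (f(theta + ei + ej) - f(theta + ei - ej) -
         f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
  }
  H
}

# fitted-CDF closure for a fit (used by the GOF machinery and plots)
fit_cdf <- function(fit) {
  reg <- model_registry(fit$model)
  est <- fit$estimates
  function(t) reg$cdf(t, est)
}

#' @export
print.nts_fit <- function(x, ...) {
  cat("Maximum-likelihood fit:", x$model, "\n")
  if (is.null(x$estimates)) {
    cat("  FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat("  n =", length(x$data), "\n")
  print(signif(x$estimates, 6))
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " converged:", x$converged,
      " starts:", x$n_starts, "\n")
  invisible(x)
}

#' @export
coef.nts_fit <- function(object, ...) object$estimates

#' @export
logLik.nts_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = length(object$data), class = "logLik")
}

#' @export
vcov.nts_fit <- function(object, ...) {
  H <- num_hessian(function(p) nts_loglik(p, object$data, object$model),
                   object$estimates)
  V <- solve(-H)
  dimnames(V) <- list(names(object$estimates), names(object$estimates))
  V
}

#' @export
summary.nts_fit <- function(object, ...) {
  se <- object$se
  if (is.null(se)) {
    V <- tryCatch(vcov(object), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  out <- list(fit = object, se = se,
              table = cbind(Estimate = object$estimates,
                            `Std. Error` = if (is.null(se)) NA_real_ else se))
  class(out) <- "summary.nts_fit"
  out
}

#' @export
print.summary.nts_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(signif(x$table, 6))
  invisible(x)
}

#' @export
simulate.nts_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$data)
  e <- object$estimates
  reg <- model_registry(object$model)
  draw <- function() {
    if (object$model == "nts-weibull")
      return(rntsw(n, e[1], e[2], e[3]))
    u <- pmin(pmax(stats::runif(n), 1e-12), 1 - 1e-12)
    vapply(u, function(ui) {
      stats::uniroot(function(t) reg$cdf(t, e) - ui,
                     lower = 1e-12, upper = 1e12, tol = 1e-10,
                     extendInt = "upX")$root
    }, numeric(1))
  }
  as.data.frame(replicate(nsim, draw(), simplify = FALSE),
                col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
residuals.nts_fit <- function(object, type = c("cox-snell"), ...) {
  type <- match.arg(type)
  Fhat <- fit_cdf(object)(object$data)
  -log(pmax(1 - Fhat, 1e-300))   # unit-exponential if the model is right
}

#' @export
plot.nts_fit <- function(x, ...) {
  d <- sort(x$data); n <- length(d)
  Fh <- fit_cdf(x)(d)
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(stats::ecdf(d), main = paste("Fitted CDF:", x$model),
                 xlab = "t", ylab = "F(t)")
  graphics::lines(d, Fh, col = 2, lwd = 2)
  graphics::plot((seq_len(n) - 0.5) / n, Fh, xlab = "empirical",
                 ylab = "fitted", main = "PP plot")
  graphics::abline(0, 1, col = 2)
  invisible(x)
}

#' Profile log-likelihood of a fitted model
#'
#' For each grid value of one parameter, re-maximizes the likelihood over
#' the remaining parameters (started from the fitted values). Grid points
#' whose inner optimization fails are flagged, not dropped.
#'
#' @param fitted an \code{"nts_fit"} object.
#' @param which parameter name to profile.
#' @param grid numeric grid of values; default is an interval around the
#'   estimate.
#' @param length.out grid size when \code{grid} is NULL.
#' @param ... unused.
#' @return data.frame with columns \code{value}, \code{loglik},
#'   \code{converged}.
#' @export
profile.nts_fit <- function(fitted, which, grid = NULL, length.out = 21, ...) {
  reg <- model_registry(fitted$model)
  j <- match(which, reg$parnames)
  if (is.na(j)) stop("unknown parameter: ", which, call. = FALSE)
  est <- fitted$estimates
  if (is.null(grid)) {
    lo <- max(reg$lower[j], est[j] * 0.5)
    hi <- min(reg$upper[j], est[j] * 1.5)
    grid <- seq(lo, hi, length.out = length.out)
  }
  rest <- setdiff(seq_along(est), j)
  prev <- est[rest]   # warm start: carry the previous grid point's solution
  out <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    v <- grid[gi]
    if (length(rest) == 0) {
      out[[gi]] <- data.frame(value = v,
                              loglik = nts_loglik(v, fitted$data, fitted$model),
                              converged = TRUE)
      next
    }
    nll <- function(q) {
      p <- numeric(length(est)); p[j] <- v; p[rest] <- q
      val <- nts_loglik(p, fitted$data, fitted$model)
      if (!is.finite(val)) 1e10 else -val
    }
    cands <- unique(list(prev, est[rest], prev * 0.7, prev * 1.4))
    o <- NULL
    for (s0 in cands) {
      s0 <- pmin(pmax(s0, reg$lower[rest]), reg$upper[rest])
      oi <- tryCatch(stats::optim(s0, nll, method = "L-BFGS-B",
                                  lower = reg$lower[rest], upper = reg$upper[rest],
                                  control = list(factr = 1e4, maxit = 300)),
                     error = function(e) NULL)
      if (!is.null(oi) && oi$value < 1e9 && (is.null(o) || oi$value < o$value))
        o <- oi
    }
    if (is.null(o)) {
      out[[gi]] <- data.frame(value = v, loglik = NA_real_, converged = FALSE)
    } else {
      prev <- o$par
      out[[gi]] <- data.frame(value = v, loglik = -o$value,
                              converged = o$convergence == 0)
    }
  }
  do.call(rbind, out)
}

#' Descriptive summary of a lifetime sample
#'
#' Minimum, maximum, mean, unbiased variance, SD, median, quartiles by
#' linear interpolation, range, moment skewness \eqn{m_3/m_2^{3/2}} and raw
#' (non-excess) moment kurtosis \eqn{m_4/m_2^2}. For a constant sample the
#' shape measures are undefined and reported as \code{NA}.
#'
#' @param x numeric lifetimes, length >= 2.
#' @return named list.
#' @examples
#' lifetime_summary(survival_times())$mean   # 9.366
#' @export
lifetime_summary <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  m <- mean(x)
  ctr <- x - m
  m2 <- mean(ctr^2); m3 <- mean(ctr^3); m4 <- mean(ctr^4)
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  list(
    n = length(x),
    smallest = min(x), largest = max(x),
    mean = m, variance = stats::var(x), sd = stats::sd(x),
    median = stats::median(x),
    q1 = qs[1], q3 = qs[2], range = max(x) - min(x),
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_
  )
}
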