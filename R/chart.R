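#' Percentile constant of the amplified sine-Weibull on the exponent scale
#'
#' \deqn{\eta_q = -\log\left[1 - \frac{2}{\pi}\sin^{-1}
#'   \left(\frac{\lambda q}{\lambda - 1 + q}\right)\right]}
#' links the monitored percentile level \eqn{q} of the lifetime to the
#' Weibull exponent scale: the \eqn{q}-percentile satisfies
#' \eqn{\alpha t_q^\delta = \eta_q}.
#'
#' @param lambda amplification parameter, > 1.
#' @param q percentile level in (0, 1).
#' @return positive real.
#' @examples
#' eta_q(1.5, 0.5)   # 0.77630
#' @export
eta_q <- function(lambda, q) {
  check_lambda(lambda)
  stopifnot(q > 0, q < 1)
  arg <- lambda * q / (lambda - 1 + q)
  -log1p(-2 / pi * asin(pmin(arg, 1)))
}

#' Failure probability before the truncation time of a life test
#'
#' Probability that an item fails before the test time \eqn{t_0 = \tau\,
#' \xi_q} where \eqn{\xi_q} is the specified percentile life. In control
#' (\code{c = 1}) the Weibull exponent is \eqn{\tau^\delta \eta_q}. Under a
#' shift constant \code{c} the default \code{shift = "scale"} variant
#' multiplies the Weibull scale \eqn{1/\alpha} by \eqn{c}, giving exponent
#' \eqn{\tau^\delta \eta_q / c}; this is the variant under which the
#' published run-length tables for this chart are reproducible. The
#' literal percentile-ratio reading, exponent \eqn{(\tau/c)^\delta \eta_q},
#' is available as \code{shift = "percentile"} for reference.
#'
#' @param tau truncation multiplier (test time / percentile life), > 0.
#' @param delta Weibull shape of the in-control process.
#' @param lambda amplification parameter of the in-control process.
#' @param q monitored percentile level (default 0.5, median life).
#' @param c shift constant; 1 = in control. \code{p_fail} is strictly
#'   decreasing in \code{c}.
#' @param shift shift semantics, \code{"scale"} (default) or
#'   \code{"percentile"}.
#' @return failure probability in (0, 1).
#' @examples
#' p_fail(0.948, delta = 2.5, lambda = 1.5)            # 0.4367
#' p_fail(0.773, delta = 0.42771, lambda = 1.02405)    # 0.39527
#' @export
p_fail <- function(tau, delta, lambda, q = 0.5, c = 1,
                   shift = c("scale", "percentile")) {
  shift <- match.arg(shift)
  stopifnot(tau > 0, delta > 0, c > 0)
  eta <- eta_q(lambda, q)
  expo <- switch(shift,
                 scale = tau^delta * eta / c,
                 percentile = (tau / c)^delta * eta)
  SG <- exp(-expo)
  s <- sin(pi / 2 * (1 - SG))
  oms <- 2 * sin(pi / 4 * SG)^2
  s * (lambda - 1) / ((lambda - 1) + oms)
}

#' np-chart control limits
#'
#' \deqn{UCL = np_0 + k\sqrt{np_0(1-p_0)}, \qquad
#'       LCL = \max\{0,\; np_0 - k\sqrt{np_0(1-p_0)}\}.}
#' Integer decision bounds are the floors of the raw limits.
#'
#' @param n subgroup size.
#' @param p0 in-control failure probability.
#' @param k chart coefficient, >= 0.
#' @return list with \code{lcl_raw}, \code{ucl_raw}, \code{lcl_int},
#'   \code{ucl_int}.
#' @examples
#' control_limits(30, p_fail(0.948, 2.5, 1.5), 2.981)  # integer limits 5, 21
#' @export
control_limits <- function(n, p0, k) {
  stopifnot(n >= 1, p0 > 0, p0 < 1, k >= 0)
  half <- k * sqrt(n * p0 * (1 - p0))
  ucl <- n * p0 + half
  lcl <- max(0, n * p0 - half)
  list(lcl_raw = lcl, ucl_raw = ucl,
       lcl_int = floor(lcl), ucl_int = floor(ucl))
}

# integer in-control decision set {dlo, ..., floor(ucl)}: counts strictly
# above the floored lower limit when LCL > 0; all counts from 0 when the
# lower limit is clipped at zero (a count below zero is impossible).
chart_dlo <- function(lcl_raw) if (lcl_raw > 0) floor(lcl_raw) + 1 else 0

#' Probability that a subgroup count falls inside the control limits
#'
#' Binomial probability of the integer in-control set
#' \eqn{\{d_{lo}, \dots, \lfloor UCL \rfloor\}} where \eqn{d_{lo} =
#' \lfloor LCL\rfloor + 1} for a positive lower limit and 0 for a clipped
#' one.
#'
#' @param n subgroup size.
#' @param p failure probability per item (degenerate 0/1 allowed: the
#'   count is then deterministic).
#' @param lcl_raw,ucl_raw raw control limits.
#' @return probability in [0, 1] (0 when the set is empty).
#' @export
in_control_prob <- function(n, p, lcl_raw, ucl_raw) {
  stopifnot(p >= 0, p <= 1)
  dlo <- chart_dlo(lcl_raw)
  dhi <- floor(ucl_raw)
  if (dlo > dhi) return(0)
  stats::pbinom(dhi, n, p) - if (dlo > 0) stats::pbinom(dlo - 1, n, p) else 0
}

#' Average run length of the np chart
#'
#' \eqn{ARL = 1/(1 - P_{in})}; returns \code{Inf} when the in-control
#' probability is 1 to machine precision.
#'
#' @inheritParams in_control_prob
#' @return ARL >= 1 (possibly \code{Inf}).
#' @export
arl <- function(n, p, lcl_raw, ucl_raw) {
  pic <- in_control_prob(n, p, lcl_raw, ucl_raw)
  if (pic >= 1) return(Inf)
  1 / (1 - pic)
}

#' Design an np control chart for percentile life
#'
#' Deterministic grid search over the chart coefficient \code{k} and the
#' truncation multiplier \code{tau} for a design whose in-control average
#' run length lands in \eqn{[r_0, r_0(1+slack)]}. Among feasible pairs the
#' one minimizing \eqn{ARL_0 - r_0} is returned. Note that many (k, tau)
#' pairs are near-equivalent: the integer decision bounds make \eqn{ARL_0}
#' piecewise-constant in (k, tau), and \eqn{\lfloor LCL \rfloor} can jump
#' at integer crossings under small rounding of the constants.
#'
#' @param n subgroup size.
#' @param delta,lambda in-control process parameters.
#' @param r0 target in-control ARL, > 1.
#' @param q monitored percentile level (default median).
#' @param xi0 optional specified percentile life; when given, the absolute
#'   test time \code{t0 = tau * xi0} is reported.
#' @param k_grid,tau_grid search grids (defaults: k in [2, 4] and tau in
#'   (0, 1.25], both in steps of 0.001).
#' @param slack feasibility window above \code{r0} (default 2\%).
#' @return object of class \code{"np_chart_design"}: list with \code{n},
#'   \code{q}, \code{delta}, \code{lambda}, \code{k}, \code{tau},
#'   \code{p0}, raw and integer limits, \code{arl0}, and \code{t0} when
#'   \code{xi0} is given.
#' @examples
#' d <- design_chart(30, delta = 2.5, lambda = 1.5, r0 = 370)
#' d$arl0
#' @export
design_chart <- function(n, delta, lambda, r0, q = 0.5, xi0 = NULL,
                         k_grid = seq(2, 4, by = 0.001),
                         tau_grid = seq(0.001, 1.25, by = 0.001),
                         slack = 0.02) {
  stopifnot(n >= 1, r0 >= 1)
  p0s <- vapply(tau_grid, p_fail, numeric(1), delta = delta, lambda = lambda, q = q)
  best <- NULL
  for (i in seq_along(tau_grid)) {
    p0 <- p0s[i]
    if (p0 <= 0 || p0 >= 1) next
    half <- k_grid * sqrt(n * p0 * (1 - p0))
    ucl <- n * p0 + half
    lcl <- pmax(0, n * p0 - half)
    dlo <- ifelse(lcl > 0, floor(lcl) + 1, 0)
    dhi <- floor(ucl)
    pic <- stats::pbinom(pmin(dhi, n), n, p0) -
      ifelse(dlo > 0, stats::pbinom(dlo - 1, n, p0), 0)
    a0 <- ifelse(pic < 1, 1 / (1 - pic), Inf)
    ok <- which(a0 >= r0 & a0 <= r0 * (1 + slack))
    if (length(ok)) {
      j <- ok[which.min(a0[ok])]
      if (is.null(best) || a0[j] < best$arl0)
        best <- list(k = k_grid[j], tau = tau_grid[i], p0 = p0,
                     lcl_raw = lcl[j], ucl_raw = ucl[j], arl0 = a0[j])
    }
  }
  if (is.null(best))
    stop("no feasible (k, tau) design for r0 = ", r0, " at n = ", n,
         "; try a larger slack or subgroup size", call. = FALSE)
  out <- list(n = as.integer(n), q = as.numeric(q), delta = as.numeric(delta),
              lambda = as.numeric(lambda),
              k = as.numeric(best$k), tau = as.numeric(best$tau),
              p0 = as.numeric(best$p0),
              lcl_raw = as.numeric(best$lcl_raw),
              ucl_raw = as.numeric(best$ucl_raw),
              lcl_int = floor(best$lcl_raw), ucl_int = floor(best$ucl_raw),
              arl0 = as.numeric(best$arl0), r0 = r0,
              t0 = if (!is.null(xi0)) as.numeric(best$tau * xi0) else NULL,
              xi0 = if (!is.null(xi0)) as.numeric(xi0) else NULL)
  class(out) <- "np_chart_design"
  out
}

#' Assemble a chart design from known constants
#'
#' Builds the same \code{"np_chart_design"} object as
#' \code{\link{design_chart}} but from explicitly supplied constants
#' \code{(k, tau)}, e.g. published ones.
#'
#' @inheritParams design_chart
#' @param k chart coefficient.
#' @param tau truncation multiplier.
#' @return an \code{"np_chart_design"} object.
#' @examples
#' chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)$arl0   # ~370.7
#' @export
chart_design <- function(n, delta, lambda, k, tau, q = 0.5, xi0 = NULL) {
  p0 <- as.numeric(p_fail(tau, delta, lambda, q))
  cl <- control_limits(n, p0, k)
  out <- list(n = as.integer(n), q = as.numeric(q), delta = as.numeric(delta),
              lambda = as.numeric(lambda), k = as.numeric(k),
              tau = as.numeric(tau), p0 = p0,
              lcl_raw = as.numeric(cl$lcl_raw), ucl_raw = as.numeric(cl$ucl_raw),
              lcl_int = cl$lcl_int, ucl_int = cl$ucl_int,
              arl0 = as.numeric(arl(n, p0, cl$lcl_raw, cl$ucl_raw)), r0 = NULL,
              t0 = if (!is.null(xi0)) as.numeric(tau * xi0) else NULL,
              xi0 = if (!is.null(xi0)) as.numeric(xi0) else NULL)
  class(out) <- "np_chart_design"
  out
}

#' @export
print.np_chart_design <- function(x, ...) {
  cat("np chart design (truncated life test)\n")
  cat(sprintf("  process: delta = %g, lambda = %g, monitored percentile q = %g\n",
              x$delta, x$lambda, x$q))
  cat(sprintf("  n = %d, k = %g, tau = %g, p0 = %.5f\n", x$n, x$k, x$tau, x$p0))
  cat(sprintf("  limits: LCL = %.4f, UCL = %.4f (integer in-control set %d..%d)\n",
              x$lcl_raw, x$ucl_raw, chart_dlo(x$lcl_raw), x$ucl_int))
  cat(sprintf("  ARL0 = %.2f\n", x$arl0))
  if (!is.null(x$t0)) cat(sprintf("  test time t0 = %g\n", x$t0))
  invisible(x)
}

#' Out-of-control ARL profile over a grid of shift constants
#'
#' Keeps the in-control limits fixed and evaluates the shifted failure
#' probability and the resulting run length at each shift constant
#' \code{c}; the entry at \code{c = 1} equals the in-control ARL exactly.
#'
#' @param design an \code{"np_chart_design"}.
#' @param c_grid shift constants (default the conventional 0.1 ... 4 grid).
#' @param shift shift semantics passed to \code{\link{p_fail}}.
#' @return data.frame with columns \code{c}, \code{p1}, \code{arl1}.
#' @examples
#' d <- chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)
#' arl_profile(d, c(0.5, 1, 2))
#' @export
arl_profile <- function(design, c_grid = c(seq(0.1, 1, 0.1), 1.05,
                                           seq(1.1, 2, 0.1), 3, 4),
                        shift = "scale") {
  stopifnot(inherits(design, "np_chart_design"))
  p1 <- vapply(c_grid, function(cc)
    p_fail(design$tau, design$delta, design$lambda, design$q, c = cc,
           shift = shift), numeric(1))
  arl1 <- vapply(p1, function(p) arl(design$n, p, design$lcl_raw, design$ucl_raw),
                 numeric(1))
  data.frame(c = c_grid, p1 = p1, arl1 = arl1)
}

#' Apply an np chart to subgroup failure counts
#'
#' Flags each subgroup in or out of control against the design's integer
#' decision set: in-control iff \eqn{d_{lo} \le D_i \le \lfloor UCL
#' \rfloor}. The decision agrees exactly with membership in the summation
#' set of \code{\link{in_control_prob}}.
#'
#' @param counts integer failure counts per subgroup, each in [0, n].
#' @param design an \code{"np_chart_design"}.
#' @return object of class \code{"np_chart_app"}: data.frame with columns
#'   \code{subgroup}, \code{D}, \code{in_control}, plus attributes
#'   \code{design} and \code{signals}.
#' @examples
#' d <- chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)
#' apply_chart(c(10, 14, 25), d)
#' @export
apply_chart <- function(counts, design) {
  stopifnot(inherits(design, "np_chart_design"))
  if (any(counts != round(counts)) || any(counts < 0))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(counts > design$n))
    stop("count exceeds subgroup size n = ", design$n, call. = FALSE)
  dlo <- chart_dlo(design$lcl_raw)
  dhi <- floor(design$ucl_raw)
  out <- data.frame(subgroup = seq_along(counts), D = as.integer(counts),
                    in_control = counts >= dlo & counts <= dhi)
  attr(out, "design") <- design
  attr(out, "signals") <- sum(!out$in_control)
  class(out) <- c("np_chart_app", "data.frame")
  out
}

#' @export
print.np_chart_app <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("np chart application: %d subgroups, %d signal(s)\n",
              nrow(x), attr(x, "signals")))
  cat(sprintf("  decision set: %d..%d (LCL = %.4f, UCL = %.4f)\n",
              chart_dlo(d$lcl_raw), floor(d$ucl_raw), d$lcl_raw, d$ucl_raw))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.np_chart_app <- function(x, ...) {
  d <- attr(x, "design")
  graphics::plot(x$subgroup, x$D, type = "b", pch = ifelse(x$in_control, 19, 4),
                 col = ifelse(x$in_control, 1, 2), xlab = "subgroup",
                 ylab = "failure count D",
                 ylim = range(0, x$D, d$ucl_raw * 1.05), ...)
  graphics::abline(h = c(d$lcl_raw, d$ucl_raw), lty = 2, col = 4)
  graphics::abline(h = d$n * d$p0, lty = 3)
  invisible(x)
}

#' Empirical control limits from an observed mean failure count
#'
#' When the in-control failure probability is unknown the limits are
#' estimated from the average subgroup count \eqn{\bar D}:
#' \eqn{\bar D \pm k\sqrt{\bar D(1 - \bar D/n)}}, lower limit clipped at 0.
#' With \eqn{\bar D = n p_0} this reproduces \code{\link{control_limits}}
#' exactly.
#'
#' @param dbar mean failure count, in [0, n].
#' @param n subgroup size.
#' @param k chart coefficient.
#' @return list with \code{lcl_raw}, \code{ucl_raw}.
#' @export
empirical_limits <- function(dbar, n, k) {
  stopifnot(dbar >= 0, dbar <= n, k >= 0)
  half <- k * sqrt(dbar * (1 - dbar / n))
  list(lcl_raw = max(0, dbar - half), ucl_raw = dbar + half)
}

#' Percentile life of the amplified sine-Weibull process
#'
#' The monitored quality characteristic of the chart: the q-percentile of
#' the lifetime distribution, identical to \code{\link{qntsw}}.
#'
#' @param q percentile level in (0, 1).
#' @param delta,alpha,lambda distribution parameters.
#' @return time.
#' @examples
#' percentile_life(0.5, 0.42771, 0.88512, 1.02405)  # ~6.65
#' @export
percentile_life <- function(q, delta, alpha, lambda) {
  qntsw(q, delta, alpha, lambda)
}

#' Reconstruct subgroup failure counts from individual lifetimes
#'
#' Utility for feeding individual survival times to \code{apply_chart}:
#' splits the series into consecutive subgroups of size \code{n} (dropping
#' a trailing partial subgroup) and counts, per subgroup, the items that
#' failed before the test time \code{t0}. This grouping is a
#' reconstruction convention, not part of the chart definition.
#'
#' @param times individual lifetimes in observation order.
#' @param n subgroup size.
#' @param t0 truncation (test) time.
#' @return integer vector of counts.
#' @export
counts_from_times <- function(times, n, t0) {
  stopifnot(n >= 1, t0 > 0)
  m <- floor(length(times) / n)
  if (m == 0) stop("fewer observations than one subgroup", call. = FALSE)
  grp <- rep(seq_len(m), each = n)
  as.integer(tapply(times[seq_len(m * n)] < t0, grp, sum))
}
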