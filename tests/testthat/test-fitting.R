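test_that("the log-likelihood equals the expanded closed form and the sum of log densities", {
  x <- survival_times()
  p <- printed_ntsw
  n <- length(x)
  G <- 1 - exp(-p["alpha"] * x^p["delta"])
  s <- sin(pi / 2 * G)
  lg <- log(p["alpha"]) + log(p["delta"]) + (p["delta"] - 1) * log(x) -
    p["alpha"] * x^p["delta"]
  expanded <- n * log(p["lambda"]) + n * log(p["lambda"] - 1) + sum(lg) +
    n * log(pi) - n * log(2) + sum(log(cos(pi / 2 * G))) -
    2 * sum(log(p["lambda"] - s))
  expect_equal(nts_loglik(unname(p), x), unname(expanded), tolerance = 1e-9)
  expect_equal(nts_loglik(unname(p), x),
               sum(dntsw(x, p[1], p[2], p[3], log = TRUE)), tolerance = 1e-12)
  # single observation
  expect_equal(nts_loglik(c(1.2, 0.5, 1.3), 2.5),
               dntsw(2.5, 1.2, 0.5, 1.3, log = TRUE))
  # finite at the lambda bound for interior data
  expect_true(is.finite(nts_loglik(c(1, 0.5, 1 + 1e-6), c(1, 2, 3))))
  # out-of-support data gives -Inf, not an error
  expect_identical(nts_loglik(c(1, 0.5, 1.5), c(1, -2, 2)), -Inf)
  # invalid parameters likewise
  expect_identical(nts_loglik(c(-1, 0.5, 1.5), c(1, 2)), -Inf)
})

test_that("multi-start fitting is at least as good as the published estimates and every start", {
  x <- survival_times()
  fit <- nts_fit(x)
  expect_s3_class(fit, "nts_fit")
  expect_gte(fit$loglik, nts_loglik(unname(printed_ntsw), x))
  # never worse than any supplied starting point
  reg <- ntsg:::model_registry("nts-weibull")
  for (s0 in reg$starts(x)) expect_gte(fit$loglik, nts_loglik(s0, x))
  # the published triple sits on the flat amplification ridge: the fitted
  # lambda lands close to it even though delta/alpha differ
  expect_lt(abs(fit$estimates["lambda"] - printed_ntsw["lambda"]) /
              printed_ntsw["lambda"], 0.02)
  # plain Weibull: the fit dominates the published pair too
  wfit <- nts_fit(x, "weibull")
  wref <- sum(ntsg:::competitor_lpdf(x, "weibull", printed_weibull))
  expect_gte(wfit$loglik, wref)
  expect_equal(unname(wfit$estimates["delta"]), unname(printed_weibull["delta"]),
               tolerance = 0.02)
})

test_that("parameters are recovered from large simulated samples", {
  set.seed(31)
  x <- rntsw(5000, 0.8, 1.0, 1.4)
  fit <- nts_fit(x, start = c(0.8, 1.0, 1.4), se = TRUE)
  expect_true(fit$converged)
  if (!is.null(fit$se)) {
    expect_lt(abs(fit$estimates["delta"] - 0.8), 4 * fit$se["delta"] + 0.02)
    expect_lt(abs(fit$estimates["alpha"] - 1.0), 4 * fit$se["alpha"] + 0.05)
  } else {
    expect_lt(abs(fit$estimates["delta"] - 0.8), 0.1)
    expect_lt(abs(fit$estimates["alpha"] - 1.0), 0.2)
  }
  # the scaled score is ~ 0 at an interior optimum
  g <- sapply(seq_along(fit$estimates), function(j) {
    h <- 1e-5 * (1 + abs(fit$estimates[j]))
    e <- rep(0, 3); e[j] <- h
    (nts_loglik(fit$estimates + e, x) - nts_loglik(fit$estimates - e, x)) / (2 * h)
  })
  expect_lt(max(abs(g * (1 + abs(fit$estimates)))) / length(x), 0.05)
})

test_that("the profile likelihood is consistent with the fit on well-identified data", {
  set.seed(42)
  y <- rntsw(500, 2.5, 2.2, 1.5)
  fit <- nts_fit(y)
  for (w in c("delta", "alpha")) {
    pr <- profile(fit, w)
    expect_true(all(is.finite(pr$loglik)))
    step <- diff(pr$value[1:2])
    expect_lt(abs(pr$value[which.max(pr$loglik)] - fit$estimates[w]),
              step + 1e-8)
    # unimodal: one sign change of the finite differences
    d <- diff(pr$loglik); d <- d[abs(d) > 1e-7]
    s <- sign(d)
    expect_lte(length(rle(s[s != 0])$values), 2)
  }
  # at the estimate itself the profile reproduces the fitted log-likelihood
  pr0 <- profile(fit, "delta", grid = fit$estimates["delta"])
  expect_equal(pr0$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("on the bundled data the amplification profile rises toward the lower boundary", {
  # the likelihood ridge of this family: profile increases as lambda -> 1+
  x <- survival_times()
  fit <- nts_fit(x)
  pr <- profile(fit, "lambda", grid = c(1 + 1e-6, 1.01, 1.05, 1.2, 1.5))
  expect_true(all(diff(pr$loglik) < 0))
  expect_gt(pr$loglik[1], fit$loglik)
})

test_that("fit methods behave like standard modelling objects", {
  set.seed(5)
  x <- rntsw(200, 1.5, 0.8, 1.5)
  fit <- nts_fit(x)
  expect_named(coef(fit), c("delta", "alpha", "lambda"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3)
  expect_equal(attr(ll, "nobs"), 200)
  expect_output(print(fit), "Maximum-likelihood fit")
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(dim(sim), c(200, 2))
  expect_true(all(sim > 0))
  r <- residuals(fit)
  # Cox-Snell residuals are ~ unit exponential under the fitted model
  expect_equal(mean(r), 1, tolerance = 0.25)
  expect_error(nts_fit(c(1, 2), "weibull"), "at least 3")
  expect_error(nts_fit(c(1, -1, 2)), "positive")
})

test_that("the sample summary reproduces the published descriptive row", {
  x <- survival_times()
  s <- lifetime_summary(x)
  expect_identical(s$n, 128L)
  expect_equal(s$smallest, 0.08)
  expect_equal(s$largest, 79.05)
  expect_equal(s$mean, 9.366, tolerance = 1e-3)
  expect_equal(s$variance, 110.425, tolerance = 1e-5)
  expect_equal(s$sd, 10.50833, tolerance = 1e-6)
  expect_equal(s$median, 6.395)
  expect_equal(s$q1, 3.348, tolerance = 1e-3)
  expect_equal(s$q3, 11.838, tolerance = 1e-3)
  expect_equal(s$range, 78.97)
  expect_equal(s$skewness, 3.286569, tolerance = 1e-6)
  expect_equal(s$kurtosis, 18.48308, tolerance = 1e-6)  # raw m4/m2^2
  # constant sample: shape measures undefined
  cs <- lifetime_summary(rep(2, 10))
  expect_identical(cs$variance, 0)
  expect_true(is.na(cs$skewness) && is.na(cs$kurtosis))
})
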