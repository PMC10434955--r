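test_that("the percentile constant eta_q matches hand evaluation and vanishes as q -> 0", {
  expect_equal(eta_q(1.5, 0.5), 0.77630, tolerance = 1e-4)
  expect_equal(eta_q(1.02405, 0.5), 1.99039, tolerance = 1e-4)
  expect_lt(eta_q(1.5, 1e-9), 1e-8)
  expect_error(eta_q(1.0, 0.5), "lambda")
  expect_error(eta_q(1.5, 0), "q > 0")
})

test_that("in-control failure probabilities reproduce the published chain", {
  expect_equal(p_fail(0.948, 2.5, 1.5), 0.4367, tolerance = 0.001 / 0.4367)
  expect_equal(p_fail(0.773, 0.42771, 1.02405), 0.39527,
               tolerance = 0.002 / 0.39527)
  # at c = 1 the two shift variants coincide
  expect_identical(p_fail(0.948, 2.5, 1.5, c = 1, shift = "scale"),
                   p_fail(0.948, 2.5, 1.5, c = 1, shift = "percentile"))
})

test_that("the shifted failure probability is strictly decreasing and matches hand arithmetic", {
  cc <- seq(0.2, 4, by = 0.1)
  p1 <- vapply(cc, function(c) p_fail(0.948, 2.5, 1.5, c = c), numeric(1))
  expect_true(all(diff(p1) < 0))
  # scale-shift value at c = 2, hand evaluation of the exponent tau^delta eta/c
  expo <- 0.948^2.5 * eta_q(1.5, 0.5) / 2
  G <- 1 - exp(-expo); s <- sin(pi / 2 * G)
  hand <- 1 - 1.5 * (1 - s) / (1.5 - s)
  expect_equal(p_fail(0.948, 2.5, 1.5, c = 2), hand, tolerance = 1e-12)
  expect_equal(hand, 0.2056, tolerance = 1e-3)
})

test_that("control limits and their integer bounds match the worked designs", {
  cl <- control_limits(30, p_fail(0.948, 2.5, 1.5), 2.981)
  expect_identical(cl$lcl_int, 5)
  expect_identical(cl$ucl_int, 21)
  cl2 <- control_limits(20, p_fail(0.773, 0.42771, 1.02405), 3.158)
  expect_equal(cl2$ucl_raw, 14.8103, tolerance = 1e-4)
  expect_identical(cl2$lcl_int, 1)
  cl0 <- control_limits(25, 0.3, 0)
  expect_equal(cl0$lcl_raw, cl0$ucl_raw)
  expect_equal(cl0$ucl_raw, 25 * 0.3)
})

test_that("the in-control probability equals brute-force pmf enumeration and Monte Carlo", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(10:60, 1)
    p <- runif(1, 0.05, 0.8)
    k <- runif(1, 0, 3.5)
    cl <- control_limits(n, p, k)
    pmf <- binom_pmf_recurrence(n, p)
    dlo <- if (cl$lcl_raw > 0) floor(cl$lcl_raw) + 1 else 0
    dhi <- min(floor(cl$ucl_raw), n)
    oracle <- if (dlo > dhi) 0 else sum(pmf[(dlo:dhi) + 1])
    expect_equal(in_control_prob(n, p, cl$lcl_raw, cl$ucl_raw), oracle,
                 tolerance = 1e-12)
  }
  # stochastic oracle: 1e6 seeded binomial draws
  cl <- control_limits(30, 0.4367, 2.981)
  set.seed(99)
  d <- rbinom(1e6, 30, 0.4367)
  dlo <- floor(cl$lcl_raw) + 1
  emp <- mean(d >= dlo & d <= floor(cl$ucl_raw))
  pic <- in_control_prob(30, 0.4367, cl$lcl_raw, cl$ucl_raw)
  se <- sqrt(pic * (1 - pic) / 1e6)
  expect_lt(abs(emp - pic), 4 * se)
  # edge behaviour
  expect_equal(in_control_prob(30, 0.5, 0, 30), 1)
  expect_equal(in_control_prob(30, 0.5, 14.2, 14.5), 0)  # empty integer set
  expect_identical(arl(30, 0.5, 0, 30), Inf)
})

test_that("run lengths of the published n = 30 design are reproduced", {
  d <- chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)
  expect_equal(d$arl0, 370.67, tolerance = 0.02)
  prof <- arl_profile(d, c(0.5, 1, 2))
  expect_equal(prof$arl1[prof$c == 1], d$arl0)  # exact identity
  expect_equal(prof$arl1[prof$c == 2], 2.51, tolerance = 0.02)
  expect_equal(prof$arl1[prof$c == 0.5], 1.18, tolerance = 0.02)
})

test_that("the ARL profile decays with increasing shift and collapses as c -> 0", {
  d <- chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)
  up <- arl_profile(d, seq(1, 4, by = 0.25))
  expect_true(all(diff(up$arl1) < 0))
  down <- arl_profile(d, c(0.05, 0.3, 0.7))
  expect_true(all(down$arl1 <= d$arl0))
  expect_equal(arl_profile(d, 0.01)$arl1, 1, tolerance = 1e-6)
})

test_that("a larger subgroup gives faster detection at matched in-control ARL", {
  d20 <- chart_design(20, 2.5, 1.5, k = 3.031, tau = 0.991)
  d30 <- chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)
  for (cc in c(1.2, 1.5, 2, 3, 4)) {
    expect_lte(arl_profile(d30, cc)$arl1, arl_profile(d20, cc)$arl1)
  }
})

test_that("the design search returns a feasible deterministic design and accepts the published constants", {
  d <- design_chart(30, 2.5, 1.5, r0 = 370)
  expect_gte(d$arl0, 370)
  expect_lte(d$arl0, 370 * 1.02)
  d2 <- design_chart(30, 2.5, 1.5, r0 = 370)
  expect_identical(d[c("k", "tau", "arl0")], d2[c("k", "tau", "arl0")])
  # published constants pass the same feasibility window
  pub <- chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)
  expect_gte(pub$arl0, 370)
  expect_lte(pub$arl0, 370 * 1.02)
  # r0 = 1 is trivially feasible (any design has ARL0 >= 1)
  expect_s3_class(design_chart(10, 2.5, 1.5, r0 = 1,
                               k_grid = seq(2, 2.2, 0.01),
                               tau_grid = seq(0.5, 1, 0.05), slack = 1e6),
                  "np_chart_design")
  expect_error(design_chart(2, 2.5, 1.5, r0 = 1e9), "feasible")
})

test_that("chart decisions agree with the in-control summation set for every count", {
  d <- chart_design(30, 2.5, 1.5, k = 2.981, tau = 0.948)
  app <- apply_chart(0:30, d)
  dlo <- if (d$lcl_raw > 0) floor(d$lcl_raw) + 1 else 0
  member <- (0:30) >= dlo & (0:30) <= floor(d$ucl_raw)
  expect_identical(app$in_control, member)
  # midpoint counts never signal
  mid <- rep(floor((d$lcl_raw + d$ucl_raw) / 2), 10)
  expect_identical(attr(apply_chart(mid, d), "signals"), 0L)
  expect_error(apply_chart(31, d), "exceeds")
  expect_error(apply_chart(-1, d), "nonnegative")
})

test_that("the fitted survival-time chart flags out-of-control subgroups", {
  # design from the fitted process with the published constants (n = 20)
  x <- survival_times()
  xi <- percentile_life(0.5, printed_ntsw[1], printed_ntsw[2], printed_ntsw[3])
  d <- chart_design(20, printed_ntsw[1], printed_ntsw[3], k = 3.158,
                    tau = 0.773, xi0 = xi)
  expect_equal(d$t0, 5.1369, tolerance = 0.01)
  counts <- counts_from_times(x, 20, d$t0)
  expect_length(counts, 6)
  app <- apply_chart(counts, d)
  expect_gt(attr(app, "signals"), 0)
})

test_that("empirical limits reduce to the theoretical ones and handle edge cases", {
  expect_equal(empirical_limits(0, 30, 3), list(lcl_raw = 0, ucl_raw = 0))
  p0 <- 0.4367
  th <- control_limits(30, p0, 2.981)
  emp <- empirical_limits(30 * p0, 30, 2.981)
  expect_equal(emp$lcl_raw, th$lcl_raw, tolerance = 1e-12)
  expect_equal(emp$ucl_raw, th$ucl_raw, tolerance = 1e-12)
  e <- empirical_limits(13.1, 30, 3)
  half <- 3 * sqrt(13.1 * (1 - 13.1 / 30))
  expect_equal(e$ucl_raw - 13.1, half)
  expect_equal(13.1 - e$lcl_raw, half)
})

test_that("percentile life matches the published median and its limiting form", {
  expect_equal(percentile_life(0.5, 0.42771, 0.88512, 1.02405), 6.64895,
               tolerance = 0.01)
  expect_equal(0.773 * percentile_life(0.5, 0.42771, 0.88512, 1.02405),
               5.1369, tolerance = 0.01)
  # lambda -> infinity: the plain sine-Weibull median
  g_med <- 2 / pi * asin(0.5)
  ref <- (-log(1 - g_med) / 0.88512)^(1 / 0.42771)
  expect_equal(percentile_life(0.5, 0.42771, 0.88512, 1e9), ref, tolerance = 1e-6)
})
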