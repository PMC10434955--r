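# Independent numerical oracles used across the test files.

# central-difference derivative of a scalar-vectorized function
num_deriv <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# binomial pmf by the multiplicative recurrence (independent of dbinom)
binom_pmf_recurrence <- function(n, p) {
  pmf <- numeric(n + 1)
  pmf[1] <- (1 - p)^n
  for (d in 0:(n - 1))
    pmf[d + 2] <- pmf[d + 1] * (n - d) / (d + 1) * p / (1 - p)
  pmf
}

# printed reference values of the published analysis, used as inputs
printed_ntsw <- c(delta = 0.42771, alpha = 0.88512, lambda = 1.02405)
printed_weibull <- c(delta = 1.05357, alpha = 0.09165)

# random parameter draws for property loops
random_ntsw_params <- function(k, seed) {
  set.seed(seed)
  data.frame(delta = runif(k, 0.3, 4),
             alpha = runif(k, 0.1, 3),
             lambda = runif(k, 1.01, 8))
}
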