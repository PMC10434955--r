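# ntsg — amplified sine-G lifetime distributions and percentile-life control charts

`ntsg` is an R package for survival/reliability analysts who need a
flexible three-parameter lifetime model and a matching attribute control
chart for monitoring percentile life under truncated life tests.

## The model

A baseline CDF G(t; κ) is mapped into the amplified sine-G family

    F(t; λ, κ) = 1 − λ(1 − sin[(π/2)G(t;κ)]) / (λ − sin[(π/2)G(t;κ)]),   λ > 1,

which amplifies the classical sine transform F = sin[(π/2)G]
(recovered as λ → ∞) and degenerates at λ = 1. With the Weibull
baseline G(t) = 1 − exp(−α t^δ) this is the **amplified sine-Weibull**
distribution: closed-form CDF/PDF/survival/hazard/quantile, monotone
*and* non-monotone (bathtub, up-down) hazard shapes, and heavy-tail
preservation (the survival ratio against the plain sine transform tends
to λ/(λ−1)).

On top of the distribution the package provides:

* `d/p/q/r`-style functions for the family (`dnts`, `pnts`, `qnts`,
  `rnts` over any `nts_baseline`) and the Weibull member (`dntsw`,
  `pntsw`, `qntsw`, `rntsw`, plus hazard/cumulative-hazard);
* maximum-likelihood fitting (`nts_fit`) with deterministic multistart
  L-BFGS-B, profile likelihoods, and standard modelling methods
  (`coef`, `logLik`, `summary`, `plot`, `simulate`, `residuals`);
* goodness-of-fit: Cramér–von Mises, Anderson–Darling,
  Kolmogorov–Smirnov with the asymptotic Kolmogorov p-value, and
  `compare_models()` across five classical competitors (Weibull,
  exponentiated Weibull, sine-Weibull, sine-inverse-Weibull,
  alpha-power-cosine Weibull);
* Monte-Carlo parameter-recovery studies (`mc_study`) with per-cell
  reproducible seeding;
* the **np control chart for percentile life**: failure-probability
  mapping (`eta_q`, `p_fail`), control limits, in-control probability,
  ARL₀/ARL₁ profiles (`arl_profile`), deterministic design search
  (`design_chart`), and application to subgroup failure counts
  (`apply_chart`);
* a bundled 128-observation survival-time dataset
  (`survival_times()`, months; Lee & Wang's classic bladder-cancer
  remission data) and a thin CLI (`inst/cli/ntsg.R`).

## Worked example

```r
library(ntsg)

x <- survival_times()
lifetime_summary(x)[c("n", "mean", "sd", "median")]
#> n = 128, mean = 9.366, sd = 10.50833, median = 6.395

fit <- nts_fit(x)            # amplified sine-Weibull, 8-start L-BFGS-B
fit
#> Maximum-likelihood fit: nts-weibull
#>   n = 128
#>    delta    alpha   lambda
#> 0.312462 1.525410 1.005320
#>   log-likelihood: -410.9267  converged: FALSE  starts: 8

gof_report(fit)[c("ks", "ks_pvalue")]
#> KS = 0.04834  (p = 0.9259)
```

The fitted shape δ̂ < 1 says the hazard is decreasing overall; the
amplification λ̂ sits near its lower boundary — the likelihood is very
flat in λ (a ridge; `converged: FALSE` records that the line search
stalled there), so λ̂ should be read jointly with (δ̂, α̂), not alone.
The KS distance of 0.048 with p ≈ 0.93 says the model tracks the
empirical CDF closely.

Designing and reading a chart for a process with δ = 2.5, λ = 1.5,
target in-control ARL 370:

```r
d <- chart_design(30, delta = 2.5, lambda = 1.5, k = 2.981, tau = 0.948)
d
#> np chart design (truncated life test)
#>   process: delta = 2.5, lambda = 1.5, monitored percentile q = 0.5
#>   n = 30, k = 2.981, tau = 0.948, p0 = 0.43669
#>   limits: LCL = 5.0026, UCL = 21.1988 (integer in-control set 6..21)
#>   ARL0 = 370.67

arl_profile(d, c(0.5, 1, 2))
#>     c        p1       arl1
#> 1 0.5 0.7922052   1.181484
#> 2 1.0 0.4366911 370.669078
#> 3 2.0 0.2056020   2.513851
```

Each subgroup of 30 items is tested for t₀ = 0.948 × ξ₀ time units
(ξ₀ the specified median life); 43.7 % of items fail by t₀ when the
process is in control, a false alarm occurs every ~371 subgroups, and a
halving of the life scale (c = 2) is caught within ~2.5 subgroups.

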