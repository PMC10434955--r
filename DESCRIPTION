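Package: ntsg
Title: Trigonometric Sine-G Lifetime Distributions and Attribute Control Charts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the amplified trigonometric sine-G family of lifetime
    distributions and its Weibull member. Provides density, distribution,
    quantile, hazard and random-variate functions, maximum-likelihood fitting
    with multi-start bounded optimization, goodness-of-fit comparison against
    classical competitors (Cramer-von Mises, Anderson-Darling,
    Kolmogorov-Smirnov), Monte-Carlo parameter-recovery studies, and the
    design and evaluation of np attribute control charts for percentile life
    under truncated life tests (failure-probability mapping, control limits,
    average run length profiles, chart application to subgroup failure
    counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
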