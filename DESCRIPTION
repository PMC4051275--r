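Package: ratedomain
Title: Rate-Domain Analysis of Two-Alternative Choice Reaction Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing two-alternative choice reaction times in
    the rate domain, where rate is the reciprocal of reaction time.
    Provides closed-form densities and samplers for the truncated Normal,
    reciprocal truncated Normal, inverse Gaussian and two-boundary
    first-passage distributions; maximum-likelihood fitting of the
    left-truncated Normal to block rate data; a seeded synthetic-experiment
    generator with autoregressive sequential structure; preprocessing
    (dithering, reciprocal transform, exclusion rules, standardise-and-collapse
    probit diagnostics); autoregressive sequential-dependency analysis with
    AR-to-MA conversion, steady-state gains and density convolution;
    repeat/alternate laterality-history analysis; and an expected-rate-of-reward
    model of optimal response timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
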