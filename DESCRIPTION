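Package: bpblr
Title: Bivariate Polynomial Binary Logit Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint regression for two correlated binary responses linked
    through two marginal logits and a log global odds ratio, each a
    polynomial in the predictors (the Plackett/Dale construction).
    Parameters are estimated by maximum likelihood with the
    Berndt-Hall-Hall-Hausman (BHHH) outer-product-of-gradients iteration;
    inference uses the simultaneous maximum likelihood ratio test and
    partial Wald tests; per-predictor polynomial degrees are selected by
    exhaustive grid search on the deviance. Includes a synthetic-data
    generator matching the model's sampling scheme, 2x2 independence
    tests, VIF diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
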