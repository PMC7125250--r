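Package: tgiagree
Title: Tumour Growth Inhibition Modelling and Inter-Operator Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how inter-operator variability in tumour size
    measurement propagates into model-based drug-effect evaluation. Provides
    a biexponential tumour growth inhibition (TGI) model, a synthetic
    generator of paired local/central lesion-diameter series with
    below-quantification handling, a nonlinear mixed-effects estimator based
    on a per-lesion Laplace approximation of the marginal likelihood
    (empirical Bayes individual estimates, relative standard errors,
    prediction-corrected visual predictive checks), and agreement statistics
    for paired measurements: relative error ratios, Bland-Altman limits of
    agreement, linear regression, profile-pattern classification and
    measurability-discordance counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
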