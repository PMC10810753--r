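Package: twingaze
Title: Twin Modelling of Infant Face-Looking Phenotypes from Raw Gaze Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for classical twin studies of infant
    looking preferences measured with eye tracking. Provides a synthetic
    twin-gaze generator (ACE-structured latent traits rendered as 120 Hz gaze
    streams over a five-object face pop-out display), extraction of
    preferential-looking phenotypes (face orienting, face preference,
    efficiency of visual exploration) with validity filtering and gaze-quality
    covariates, a full-information maximum-likelihood engine for saturated and
    ACE-family twin models (univariate and bivariate Cholesky) with
    nested-model comparison and profile-likelihood confidence intervals, and
    association statistics: tests against chance, generalized estimating
    equations with cluster-robust standard errors, and false discovery rate
    control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
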