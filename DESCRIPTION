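Package: hpagtwr
Title: Health Policy Attention Indexing and Geographically and Temporally
    Weighted Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a text-derived health policy attention (HPA) index from
    document corpora via word-embedding lexicon expansion and term-frequency
    scoring, and regresses it on socioeconomic covariates with a
    geographically and temporally weighted regression (GTWR). Includes a
    CBOW word-embedding trainer with cosine-similarity seed-set expansion,
    spacetime kernel weighting with leave-one-out cross-validated bandwidth
    selection, local weighted least squares with AICc and adjusted R-squared
    fit statistics, an OLS baseline, Moran's I with permutation inference,
    a local-coefficient nonstationarity test, and a synthetic-data generator
    (city grids, varying coefficient surfaces, covariate panels and corpora
    with known ground truth) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
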