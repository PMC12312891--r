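Package: lakecover
Title: Multitemporal Land-Cover Dynamics of a Seasonal Lake
Version: 0.1.0
Authors@R:
    person("Lakecover", "Maintainers", email = "maintainers@lakecover.dev",
           role = c("aut", "cre"))
Description: Supervised land-cover classification and multitemporal analytics
    for seasonal lake systems observed with multispectral imagery. Provides a
    Gaussian maximum-likelihood classifier, a one-vs-rest kernel support vector
    machine decision tree with an agreement-fusion refinement, accuracy
    assessment (overall/user's/producer's accuracy, Cohen's kappa, McNemar
    comparison, Jeffries-Matusita separability), per-scene class-area time
    series with descriptive statistics, Grubbs outlier screening and Pearson
    correlation, pixel-wise inundation/vegetation frequency and
    coefficient-of-variation stability mapping, land-category transfer
    matrices, and a seeded synthetic-scene generator so the whole pipeline is
    testable without satellite downloads.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
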