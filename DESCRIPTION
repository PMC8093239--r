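Package: distressbn
Title: Discrete Bayesian-Network Modelling of Psychological-Distress Risk in
    Young Adolescents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling risk and protective factors for
    psychological distress in young adolescents with discrete Bayesian
    networks. Discretizes self-report instrument scores (K10, PSQI, SCS,
    HBSC physical activity, FFQ eating, MCQ-A, MAAS-A, BIS-Brief,
    WHOQOL-BREF domains, cyberstrife flag) into node states, estimates
    conditional probability tables from cohort data by relative frequency,
    performs exact inference by variable elimination, runs what-if
    "certainty" scenarios with a percent-change statistic, and carries out
    one-way sensitivity analysis of a target posterior with respect to each
    network parameter under proportional covariation. Includes a synthetic
    cohort generator (a deterministic 64-record fixture plus seeded
    latent-factor cohorts) so every stage is testable without access to
    the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
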