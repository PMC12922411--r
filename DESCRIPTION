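Package: samine
Title: Mining, Scoring and Evaluation of Toxicity Structural Alerts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for deriving structural alerts (toxicophore candidate
    substructures) from binary-labelled SMILES datasets. Candidate fragments
    are enumerated by several strategies (circular atom environments, linear
    paths, heteroatom-seeded functional groups, recursive bond breaking, and
    predefined SMARTS catalogues), filtered by support, precision and
    Bonferroni-corrected binomial significance, and scored by precision,
    coverage rate and information gain. Alert sets can be evaluated as binary
    classifiers under a repeated 8:2 holdout protocol (ACC, PPV, MCC), merged
    into consensus benchmark sets across strategies, compared against
    reference alert collections, and combined with a fingerprint-based
    random-forest model through a conjunction decision rule. A seeded
    synthetic-data generator with implanted ground-truth toxicophores
    supports end-to-end validation without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Rcpp,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
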