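Package: ddxtopics
Title: Interpretable Differential-Diagnosis Recommendation from Clinical Text Topic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits latent Dirichlet allocation topic models to pre-tokenized
    clinical notes by collapsed Gibbs sampling, derives a Bayesian word-topic
    posterior P(t|w) that extends topic inference to out-of-corpus records,
    selects the number of topics with the Balance Similarity criterion, builds
    per-diagnosis topic profiles from records grouped by primary diagnosis,
    and ranks candidate differential diagnoses with an interpretable
    distance/angle bonus-penalty score on the document-vs-diagnosis plane.
    Includes a synthetic corpus generator with planted diagnosis and
    differential-diagnosis structure, recall-at-N evaluation against a cosine
    baseline, plane visualisation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
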