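Package: contactpred
Title: Link Prediction for Temporal Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting new link formation in temporal contact
    networks such as face-to-face proximity records. Aggregates timestamped
    contact events over a training window into a weighted undirected graph
    (flat, linearly decaying, or exponentially decaying contact weights),
    computes ten neighborhood-based link-prediction scores (common neighbors,
    Adamic/Adar, preferential attachment, Jaccard, resource allocation, and
    their weighted variants with a tunable weight-contribution exponent), and
    evaluates predictions against a testing window with precision/recall
    curves, rank-based ROC/AUC, and the DeLong paired test for correlated
    AUCs. Includes parameter sweeps over the weight exponent, the strong-tie
    threshold, and the training-window length, and a synthetic contact-stream
    generator with bursty activity, community structure, hubs, triadic
    closure, and affinity drift for fully offline experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
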