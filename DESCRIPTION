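Package: eventbtm
Title: Event-Based Topic Learning for Neuroimaging Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An event-based topic learning pipeline for full-text
    neuroimaging literature. Recognizes neuroimaging research events
    (triggers, arguments and argument roles) in sentences with a
    BiLSTM-CNN sequence tagger and a convolutional role classifier,
    models the extracted events with a biterm topic model fitted by
    collapsed Gibbs sampling, and evaluates the learned topics by
    document co-occurrence coherence and mean pairwise Kullback-Leibler
    divergence. Includes dictionary-based distant supervision, readers
    and writers for CoNLL-style BIO and role annotation formats, and a
    seeded synthetic-corpus generator with gold annotations for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
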