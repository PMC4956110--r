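Package: songscribe
Title: Hybrid Convolutional-Network/Hidden-Markov-Model Annotation of Birdsong
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic annotation of birdsong-like sequential vocalizations:
    note boundary detection, frame-wise local classification with a deep
    convolutional network, and global sequencing with a second-order Markov
    syntax model decoded by a (sub-state) hidden Markov model. Implements
    three arrangements of the boundary-detection, local-classification and
    global-sequencing steps, joint classification/timing error metrics for
    truth/prediction annotation pairs, and a seeded synthetic-song generator
    so that every stage can be trained and evaluated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
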