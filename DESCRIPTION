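Package: dyadsync
Title: Unsupervised Detection of Interpersonal Speech Synchrony in Dyadic
    Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interpersonal synchrony (entrainment) in dyadic
    conversations from frame-level acoustic feature streams. For each
    conversation two bottleneck autoencoders are trained, one per speaker,
    on that speaker's 10 ms feature frames; each speaker's frames are then
    reconstructed by the partner-trained autoencoder, yielding an ordered
    per-frame root-mean-square reconstruction-error trace whose fitted
    linear slope over normalized session time is the synchrony statistic
    (negative slope = partners becoming more similar). Includes transcript
    driven speaker segmentation, group-level aggregation (average slope and
    Pearson correlation of paired slopes), complementary half-session
    lexical similarity measures (shared word usage and word-embedding
    cosine similarity), a mel-spectrogram utility, and a synthetic dyad
    generator with controllable convergence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
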