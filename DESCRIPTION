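Package: cgbesmart
Title: Prediction of C-to-G Base-Editing Outcomes from Sequence Context
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies C-to-G base-editing outcomes from amplicon
    sequencing reads of guide RNA libraries, learns sequence-context
    (motif) preferences of C-to-G base editors by logistic regression,
    predicts per-position editing efficiency with an ensemble of windowed
    feed-forward networks over learned nucleotide embeddings, and infers
    the full distribution of edit patterns by combining per-position
    marginals with adjacent-pair odds ratios in a chain-factorized
    Bernoulli model. Ships a synthetic sgRNA-library simulator with
    exported ground truth so every stage can be trained and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
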