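Package: groundlex
Title: Zero-Shot Visual Grounding of Word Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a linear alignment from a textual word-embedding space to a
    visually grounded space by regressing image feature vectors from caption
    encodings (word-level, bag-of-words, GRU, LSTM, or stacked transformer-encoder
    bridges), then applies the alignment zero-shot to an entire vocabulary,
    including words never seen in captions. Ships the accompanying evaluation
    machinery: cosine/Spearman scoring on word-pair similarity and relatedness
    benchmarks, per-dataset min-max normalization and benchmark combination,
    concreteness merging with sigma-binning, nearest-neighbour listings, paired
    significance tests between embedding models, and tenfold cross-validated
    concreteness prediction with linear and multilayer-perceptron regressors.
    Includes seedable synthetic-data generators with planted ground truth so the
    full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
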