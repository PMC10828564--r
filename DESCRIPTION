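Package: dnaembed
Title: Neural and Classical Embeddings of DNA Sequences for Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes DNA sequences as Chaos Game Representation (CGR) images
    and learns fixed-dimension vector embeddings whose cosine similarity
    tracks Needleman-Wunsch global-alignment similarity. A Siamese
    convolutional or fully connected network is trained with a triplet loss
    or a ladder (ranked-tier) loss against alignment-derived ground-truth
    rankings, and compared with classical embedders: flattened frequency-CGR,
    principal component analysis, and locality-sensitive image hashes
    (average, perceptual, and wavelet hashing). Ranking fidelity is scored
    with normalized discounted cumulative gain and an exponential positional
    rank score, and a small exact cosine index supports retrieval. A
    synthetic sequence-family generator with graded per-tier mutation rates
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
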