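Package: utrlm
Title: Masked k-mer Language Models for 3'UTR Regulatory Element Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for self-supervised language modelling of
    3'UTR sequences. Sequences are tokenized into overlapping k-mers,
    a transformer encoder is pre-trained with a span-contiguous masked
    language-model objective, and fine-tuned heads score RBP binding
    windows, m6A-style modification windows and multi-label mRNA
    subcellular localization. Attention from the classification token is
    converted into per-nucleotide importance tracks, from which enriched
    7-mer motifs are extracted by hypergeometric testing with
    Benjamini-Hochberg correction and exported as position weight
    matrices in MEME minimal format. A synthetic planted-motif data
    generator makes the entire pipeline testable on one CPU with full
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
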