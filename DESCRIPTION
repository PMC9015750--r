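Package: medlit
Title: Literacy-Aware Annotation of Medical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for making medical documents accessible to readers at
    different health-literacy levels. Scores a reader's health literacy with
    a three-parameter logistic item response model (EAP ability estimation,
    marginal maximum likelihood calibration, information-based test
    shortening), recognizes medical entities in free text with a
    BiLSTM-CNN-CRF sequence tagger, links mentions to a knowledge base via
    character trigram TF-IDF nearest-neighbour candidate generation followed
    by vector-space word sense disambiguation, classifies term difficulty
    from lexical and distributional features, and annotates only the terms a
    given reader's literacy level warrants, attaching definitions and
    taxonomic relations. Includes synthetic-data generators for knowledge
    bases, tagged corpora, response matrices and vote-labelled difficulty
    datasets so every stage can be exercised without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nnet,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
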