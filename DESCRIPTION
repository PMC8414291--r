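Package: ontoMatch
Title: Biomedical Ontology Matching with Multi-Dimensional Clues and
    Reduction Anchors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns two OWL/RDF ontologies by building virtual documents
    for four clue dimensions (terminological, structural, external
    lexicon, representation learning), scoring candidate concept pairs
    with TF-IDF cosine and normalized edit similarity under thirteen
    matcher presets, and combining similarity matrices into one-to-one
    equivalence alignments. For large ontologies, extended positive and
    negative reduction anchors (LOM-PE, LOM-NE, LOM-Hybrid) prune
    ignorable similarity computations while preserving alignment
    quality. Includes OAEI alignment format I/O, precision/recall/F1
    evaluation against reference alignments, and a parameterized
    synthetic ontology-pair generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ontoMatch-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'parse-turtle.R'
    'parse-rdfxml.R'
    'ontology.R'
    'lexicon.R'
    'embeddings.R'
    'clues.R'
    'corpus.R'
    'similarity-matrix.R'
    'matchers.R'
    'reduction.R'
    'alignment.R'
    'synthetic.R'
    'pipeline.R'
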