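Package: prescsim
Title: Prescription Similarity via Self-Supervised Graph Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the similarity between multi-herb traditional Chinese
    medicine prescriptions for drug-repositioning screens. A heterogeneous
    knowledge graph linking prescriptions to diseases, symptoms, herbs, herb
    attributes (property, flavor, meridian, category), ingredients and
    protein targets is embedded with a graph convolutional encoder trained
    under the Deep Graph Infomax mutual-information objective. Target and
    candidate prescriptions are then compared by cosine similarity of their
    embeddings and by the Jaccard coefficient of their attribute sets,
    high-similarity pairs are screened against thresholds with exclusion
    rules, and hyperparameters are selected by the stability (standard
    deviation and coefficient of variation) of the similarity outputs.
    Includes a seeded synthetic knowledge-graph generator with planted
    prescription clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    e1071,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
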