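Package: digitalCMS
Title: Digital Consensus-Molecular-Subtype Scoring of Cervical Cancer
    Histology with Triplet-Ranking Multiple-Instance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the two consensus molecular subtypes (C1/C2) of
    HPV-positive cervical squamous cell carcinoma from bags of histology
    patch embeddings using a triplet-ranking multiple-instance learner,
    and profiles the downstream consequences of the prediction: Youden-cutoff
    survival stratification (Kaplan-Meier, log-rank, Cox), exemplar-region
    mining by k-means over patch embeddings, quantitative
    tumour-microenvironment statistics from nuclei-detection records, and
    DAB colour-deconvolution CD8+ scoring. A seeded synthetic-cohort
    generator emulates the external feature extractor and nuclei detector
    so that the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    pROC,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
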