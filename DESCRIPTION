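Package: mdmf
Title: Similarity-Constrained Matrix Factorization for miRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts miRNA-disease associations by weighted matrix
    factorization in which the cosine similarity between disease latent
    vectors is constrained to match an integrated disease-similarity
    matrix. Disease similarity combines DAG-based semantic similarity
    (Wang measure over MeSH-style hierarchies) with Gaussian interaction
    profile (GIP) kernel similarity computed from association profiles.
    miRNA expression values serve as confidence weights for unobserved
    association-matrix entries. Includes global and local leave-one-out
    cross-validation with ranking metrics (AUC, AUPR, F1, accuracy, MCC),
    candidate ranking for a queried disease, readers for the tab-separated
    input formats, and a seeded synthetic-data generator with planted
    low-rank structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
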