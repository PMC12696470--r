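Package: saltol
Title: Saline-Alkaline Tolerance Evaluation and Co-Expression Candidate Gene Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-method evaluation of crop saline-alkaline tolerance from
    physiological indicator panels (min-max membership-function scoring
    cross-validated by TOPSIS, with optional entropy weighting), together
    with the downstream candidate-gene discovery pipeline: change-rate
    computation and correlation, threshold-based differential-expression
    filtering with multi-set Venn intersection, a from-scratch weighted
    co-expression core (soft-threshold selection, topological overlap,
    module detection and merging, module eigengenes, module-trait
    correlation, intramodular connectivity and hub selection), and seeded
    synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
biocViews: GeneExpression, Network, Clustering, DifferentialExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
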