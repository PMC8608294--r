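Package: katzsp
Title: LncRNA-Disease Association Prediction by KATZ Walk Counting and
    Similarity-Space Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers candidate lncRNA-disease associations from a bipartite
    graph of known associations. Disease semantic similarity over a disease
    ontology DAG, lncRNA functional similarity, and Gaussian interaction
    profile kernels are integrated into a heterogeneous adjacency matrix; a
    closed-form KATZ walk-counting measure produces primary scores that are
    refined by projection in the lncRNA and disease similarity spaces
    (the KATZSP model). Includes leave-one-out cross-validation with
    ROC/AUC, novel-lncRNA and isolated-disease protocols, an attenuation
    parameter sweep, top-k candidate ranking, a planted-block synthetic
    benchmark generator, and a minimal MAT-v5 reader for deposited
    association datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), pROC, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
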