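Package: ehbcs
Title: Elite Hybrid Binary Cuckoo Search for Wrapper Feature Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for binary classification by an elite
    hybrid binary cuckoo search: Relief feature weighting parameterizes the
    sigmoid transfer function that binarizes Mantegna-sampled Levy-flight
    steps, and an elitist genetic layer (roulette selection, single-point
    crossover) replaces the classical nest-abandonment step. Includes binary
    cuckoo search, binary genetic algorithm and binary particle swarm
    baselines behind one interface, a cross-validated SVM (or fast
    nearest-centroid) fitness combining accuracy with a feature-reduction
    reward, stratified fold construction, a planted-signal synthetic data
    generator, and a repeated-runs benchmark harness reporting accuracy,
    sensitivity, specificity, precision and F-measure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, e1071, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
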