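Package: dmfconn
Title: Whole-Brain Mean-Field Modeling and Resting-State Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-brain resting-state activity with a dynamic
    mean-field neural mass model under feedback inhibition control, forwards
    it through the Balloon-Windkessel hemodynamic model, and fits the global
    coupling parameter to empirical functional connectivity by grid search.
    Also provides resting-state fMRI connectivity statistics (global and
    long-range weighted-degree connectivity, seed maps, group contrasts with
    permutation cluster correction, occurrence maps, motion censoring,
    covariate residualization), imaging-transcriptomics gene decoding with
    odds-ratio and hypergeometric enrichment, connectivity-based subject
    subtyping with cluster-index majority voting, and synthetic data
    generators with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
NeedsCompilation: yes
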