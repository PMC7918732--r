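Package: epigrn
Title: Gene Regulatory Network Inference with Epigenetic Regulators as Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers weighted gene regulatory networks from expression matrices
    using per-target tree-ensemble variance-importance scores, with both
    transcription factors and epigenetic regulators (histone modification, DNA
    methylation, chromatin remodeling, siRNA biogenesis) as predictors. Provides
    trimming to a high-confidence top-fraction network, extraction of
    process-specific subnetworks from differentially-expressed-gene lists,
    regulator influence ranking by edge-weight sums, rank-sum aggregation of
    rankings across studies, in silico target retrieval, and hypergeometric
    validation of predicted targets against experimental gene lists with genome
    or microarray-probe backgrounds. A synthetic benchmark module generates
    ground-truth regulator-target networks with planted process-regulator hubs
    so that every pipeline stage is testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, parallel, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), ranger, jsonlite, yaml, SummarizedExperiment, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
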