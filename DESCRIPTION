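Package: cereFC
Title: Region- and Cell-Type-Resolved Differential Expression for Cerebellar Fear Conditioning Studies
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for detecting region-, cell-type-,
    and learning-phase-specific transcriptional changes in spatial (Visium-style)
    and single-nucleus RNA-seq data from fear-conditioning designs with home-cage
    (HC), conditioned (CD) and tone-retrieval (TN) groups. Implements QC and
    normalization, joint expression-spatial graph fusion with Leiden clustering,
    signature-based region annotation (NNLS deconvolution, 99th-quantile
    binarization, Fisher's exact enrichment, max-odds-ratio assignment), a
    pseudo-replicate consensus differential-expression procedure built on a
    negative-binomial GLM likelihood-ratio test, hurdle-model single-nucleus DEG
    with a cellular detection rate covariate, AUC-based regulon activity scoring
    with one-sided Wilcoxon differential testing, and hypergeometric
    over-representation analysis. Ships a synthetic-data generator emulating the
    assumed data structure so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
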