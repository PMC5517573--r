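Package: ropeca
Title: Reproducibility-Optimized Peptide-Level Differential Expression
    for Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential protein expression analysis for label-free
    (in particular data-independent acquisition) proteomics.  Peptide-level
    two-group statistics are chosen from a family of t-type statistics by
    maximizing a reproducibility Z-score, the overlap of top-ranked peptides
    across group-preserving bootstrap datasets relative to permuted data.
    Peptide-level p-values are aggregated to protein level through the beta
    distribution of the median order statistic of directional p-values
    (ROPECA), with a plain t-test based variant (PECA), protein-level
    baselines, synthetic spike-in and hybrid-proteome benchmark generators,
    and partial-AUC / FDR-curve evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
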