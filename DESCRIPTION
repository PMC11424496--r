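Package: perturbLR
Title: Epigenetic-Regulator Mutations Associated with Ligand-Receptor
    Interaction Dysregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies somatic mutations of epigenetic-regulator genes that
    are statistically associated with per-sample dysregulation of
    ligand-receptor interaction pairs in tumour cohorts. For each
    ligand-receptor pair, samples whose two-gene expression vector is a
    Mahalanobis-distance outlier (iterative Grubbs' test) are flagged as
    dysregulated; mutations whose carrier samples co-occur with the
    dysregulated samples more often than expected under a
    marginal-preserving permutation null, gated by Wilcoxon rank-sum
    differential expression of the interacting genes, are selected.
    Includes downstream mutation-signature stratification, tumour-immune
    expression scores (MHC-I, CTL, cytolytic activity), hypergeometric
    gene-set enrichment, a synthetic-cohort generator with ground-truth
    labels for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
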