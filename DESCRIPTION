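Package: refstab
Title: Reference-Gene Stability Selection for qRT-PCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting stable reference (housekeeping) genes for
    quantitative real-time PCR. Screens candidate genes from an expression
    matrix (FPKM or similar) by coefficient of variation, processes
    replicate-level Ct tables, and ranks candidates with three independent
    stability algorithms: the geNorm M-value with stepwise exclusion and
    pairwise-variation analysis, the NormFinder model-based variance
    decomposition, and BestKeeper-style descriptive statistics. Rankings are
    combined into a consensus ordering, and selected reference sets are
    validated by 2^-ddCt relative quantification of target genes. A seeded
    simulator generates replicate-level Ct tables with the group/replicate
    structure of a typical multi-stress qRT-PCR experiment so the whole
    workflow can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
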