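Package: dragtrace
Title: Clonal Lineage Tracing with VDJ-Recombination DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in situ cellular barcoding systems that
    create heritable DNA barcodes through RAG-mediated VDJ-like recombination
    of a synthetic cassette. Provides a generative model of recombination
    (segment trimming, untemplated N-addition, D-segment inversion) with
    exact generation-probability (Pgen) computation by scenario-space
    summation and parameter fitting by expectation-maximization; a
    ground-truthed simulator of UMI-tagged amplicon sequencing reads from
    clone populations with compartment fate classes; UMI-consensus barcode
    calling, abundance filtering and replicate-concordance QC; filtering of
    recurrent high-Pgen barcodes; clonal fate classification, clone-size and
    incidence-based richness (chao2) estimation with labeling-efficiency
    correction, and Renyi/Simpson diversity profiles; and segmented
    (breakpoint) gamma generalized linear mixed models for longitudinal
    clonal diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    glmmTMB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
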