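Package: methylCTCF
Title: Integrative Analysis of CTCF Binding, DNA Methylation and
    Nucleosome Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how DNA methylation and nucleosome
    repositioning shape differential CTCF binding between two cellular
    conditions (e.g. wild-type versus Tet1/2 double-knockout embryonic
    stem cells). Implements a biophysical (TRAP-style) model that
    predicts CTCF binding affinity landscapes from genome sequence,
    replicate-consensus classification of common/lost/gained CTCF
    sites, sliding-window calling of differentially methylated regions
    and differential nucleosome occupancy, nucleosome repeat length and
    affinity-landscape periodicity estimation, anchor-centred average
    profiles with replicate averaging, ROC-based comparison of
    predictors of CTCF loss, feature fold-enrichment, and linkage of
    CTCF loss at domain boundaries to gene expression changes. A
    synthetic epigenome generator with a machine-readable truth
    manifest supports end-to-end validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
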