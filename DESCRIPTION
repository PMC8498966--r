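Package: macmic
Title: Mutual-Information-Adjusted Colocalization Scoring of Chromatin Feature Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores pairs of chromatin features (ChIP-seq peak tracks) by how
    much their genome-wide colocalization exceeds what their mutual dependence
    predicts. Per-gene promoter signals drive a Poisson-model mutual
    information estimate; a panel-wide least-squares regression of
    colocalization counts on mutual information yields expected counts, and
    the MACMIC score (observed minus expected colocalization, relative to
    expected) flags feature pairs that colocalize far more than their
    correlation predicts, such as bivalent H3K4me3/H3K27me3 domains. Also
    provides width-based rank-product gene ranking, ROSE-style super-enhancer
    calling with CTCF-associated (CSE) versus other (OSE) classification, an
    enlarged-typical-enhancer null simulation, and a seeded synthetic panel
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glue,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
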