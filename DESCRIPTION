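Package: teloop
Title: Transposable-Element Origins of CTCF-Anchored Chromatin Loops and TAD Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how transposable elements (TEs) supply CTCF binding
    sites that anchor chromatin loops and TAD boundaries. Implements the
    full analysis chain: PWM scanning of loop anchors and TAD boundary
    windows for CTCF motifs gated on ChIP peaks, classification of anchor
    CTCF sites as repeat-derived by a 10 bp overlap rule against
    RepeatMasker annotations, class/family/subfamily taxonomy summaries with
    a chromosome-preserving shuffle null, chain-based interval lifting with
    a configurable sequence match rate for cross-species conservation calls
    on loops and TAD boundaries, ChromHMM-based enhancer-promoter loop
    attribution with a CRISPR candidate-selection filter, and contact-matrix
    statistics (Knight-Ruiz balancing, observed/expected transforms,
    long-range intra/inter-domain interaction fractions, virtual 4C, focal
    enrichment). A deterministic two-species synthetic-data generator with
    planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
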