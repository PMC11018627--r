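Package: kdparch
Title: Domain-Architecture Classification of KdpD Sensor Kinases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies KdpD-family sensor kinase proteins across prokaryotic
    species by domain architecture and kinase capability. KdpD of the KdpDE
    two-component system is a tandem serine histidine kinase: an N-terminal
    atypical serine kinase (ASK) built on Walker A/B nucleotide-binding motifs
    and a C-terminal histidine kinase (HK) transmitter (DHp/CA domains).
    The package aligns candidate chains to an annotated reference by global
    affine-gap alignment, projects reference domain intervals and anchor
    residues onto each chain, scans for Walker motifs, assigns chain- and
    species-level architecture classes (full-length, short KdpD/Usp, split
    ASK+HK, HK-truncated, KdpD-domain-only), and cross-tabulates the classes
    against the presence of the response regulator KdpE and of a diadenylate
    cyclase. A synthetic proteome generator with planted architectures,
    motif ablations and configurable metadata correlations makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
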