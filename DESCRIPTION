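Package: luxrsolo
Title: Census of Solo LuxR Quorum-Sensing Genes in Annotated Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects LuxR-family transcriptional regulators in annotated
    bacterial genomes by a dual-domain architecture rule (an N-terminal
    autoinducer-binding domain followed by a GerE-type DNA-binding domain,
    within a plausible length range), classifies each luxR gene's chromosomal
    neighborhood into quorum-sensing circuit topologies (RI, RMI, RLI, RXMI),
    twin-luxR arrangements or solo, labels proteins as AHL-binding or
    non-AHL-binding by consensus-motif scanning, builds neighbor-joining
    similarity cladograms, computes per-clade cysteine statistics, and screens
    conserved cysteines mapped onto a TraR-type template structure for
    potential disulfide bridges.  Ships a deterministic synthetic-genome
    generator that plants cassettes of every topology class together with
    decoy genes, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    bio3d,
    phangorn,
    Biostrings,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
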