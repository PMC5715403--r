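Package: nifb
Title: Curation, Domain Architecture and Phylogenetics of NifB Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating candidate databases of the nitrogenase
    cofactor maturase NifB and related radical-SAM protein families. Implements
    a motif-fingerprint scanner over the six conserved SAM-radical motifs (HPC,
    Cx3Cx2C, ExRP, AGPG, TxTxN, Cx2CRxDAxG), three-class domain-architecture
    classification (stand-alone SAM-radical, SAM + NifX-like, and the
    three-domain NifN fusion), per-taxon architecture frequency tables,
    conserved-block alignment trimming, neighbor-joining tree construction with
    outgroup rooting, small in-silico sequence computations (protein mass,
    primer-defined truncations, growth-rate constants), and a ground-truth
    synthetic protein-family generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    phytools,
    tibble,
    dplyr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
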