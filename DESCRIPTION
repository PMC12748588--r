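Package: coevodock
Title: Coevolution-Guided Interface Inference and Coarse-Grained Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from paired multiple sequence alignments to
    docked complex models for multi-subunit protein assemblies. Implements
    paralog-matched alignment concatenation, mean-field direct coupling
    analysis with Direct Information ranking, right-tailed hypergeometric
    contact enrichment with a solvent-accessibility filter, mapping of
    crosslinking mass-spectrometry residue pairs onto coordinate models
    under a C-alpha distance criterion, and a C-alpha structure-based
    (Go-type) Langevin docking engine that accepts coevolutionary distance
    restraints. Includes a synthetic-data module (Potts-sampled alignments
    with planted inter-domain couplings, toy bead complexes, crosslink
    tables) so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
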