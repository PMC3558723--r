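Package: tcrlattice
Title: Crystal-Packing Contact Analysis of T Cell Receptor Constant Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symmetry-aware analysis of molecular packing in T cell receptor
    (TCR) crystal structures, centred on the membrane-proximal constant domain
    of the TCR alpha chain (the "Calpha" immunoglobulin-like domain). The
    package expands crystallographic symmetry to enumerate lattice neighbours,
    detects and classifies all inter-molecular contacts made by Calpha domains,
    assesses candidate Calpha-Calpha pairs for two-fold symmetry and membrane
    orientation, scans sequences for N-X-S/T glycosylation sequons with an
    efficiency rule, and ships a synthetic crystal/sequence generator with
    known ground truth so that every stage is testable without downloading
    deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
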