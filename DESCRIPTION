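Package: primap
Title: Batch PCR Primer Design with Thermodynamic Filtering and Target Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Designs forward and reverse primers from multi-FASTA datasets
    under user-set thermodynamic and compositional constraints.  Candidate
    oligos are enumerated in 5' and 3' search windows, scored with a
    nearest-neighbor melting-temperature model (SantaLucia 1998 unified
    parameters with monovalent-salt correction), filtered on length, GC
    content, GC clamp and Tm range, and screened for within-dataset
    specificity by exact strand-aware matching.  Accepted primers are mapped
    back to their targets with a re-extraction verification gate and rendered
    as per-primer alignment panels (PNG/JPEG/GIF) and per-sequence
    distribution maps with arrowed glyphs, each with a machine-readable JSON
    sidecar.  A command-line driver and a deterministic synthetic-FASTA
    generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    png,
    withr,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
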