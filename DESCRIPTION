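Package: rsecapture
Title: Capture Oligo Panel Design and Enrichment Evaluation for
    Region-Specific Extraction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs panels of 22-27 nt capture oligonucleotides for
    region-specific extraction (RSE) of genomic DNA, spacing unique,
    thermodynamically screened oligos at approximately 8 kb intervals
    across target regions of up to 1 Mb. Screens candidates by GC
    content, nearest-neighbor melting temperature, hairpin and
    homo-/hetero-dimer formation, and genome-wide uniqueness, then
    cross-screens the multiplexed set. Evaluates targeted-capture
    sequencing experiments: on-target fold enrichment, per-base read
    depth profiles, coverage fraction, and zero-coverage gap detection
    for deletion discovery, plus a recombination-distance utility for
    positional mapping. Includes an error-free capture-read simulator
    with known ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
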