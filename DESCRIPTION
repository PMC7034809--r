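Package: ccfnoise
Title: Simulation and Decomposition of Sequencing Noise in Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the background error of unique molecular
    identifier (UMI) based next-generation sequencing of circulating
    cell-free DNA (ccfDNA). Provides a branching-process PCR read simulator
    with per-error provenance (cycle of origin, sequencing layer, clonal
    hematopoiesis, patterned artifacts, spiked variants), UMI family
    grouping and consensus calling for singleton and duplex adapter
    schemes, region-gated base-level error-rate estimation, per-position
    nonreference-allele tracks, and a stepwise noise decomposition that
    quantifies error removed by CHIP filtering against matched buffy-coat
    data, patterned-position removal at configurable relatedness, and
    sample-duplicate intersection. Stand-alone calculators for index
    hopping rate, ligation efficiency, and the theoretical consensus read
    depth limit are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
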