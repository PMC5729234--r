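Package: tepbat
Title: Targeted Post-Bisulfite Methylome Analysis of LTR Retrotransposon Copies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for targeted post-bisulfite
    adaptor-tagging (TEPBAT-style) sequencing of LTR retrotransposon copies.
    Generates synthetic genomes with planted IAP-like proviruses and solo
    LTRs, simulates tag/primer paired-end bisulfite reads, maps them with a
    unique-anchor rule under reduced bisulfite alphabets, computes per-copy
    CpG methylation levels with call-count filtering and low/medium/high
    binning, annotates 5'/3'/solo LTR structure, summarises subfamily- and
    feature-specific hypomethylation, clusters copies by neighbor joining
    with bootstrap to locate hypomethylated clades, and tests clade-specific
    transcription-factor motif enrichment by PWM scanning with exact
    p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
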