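Package: ampedit
Title: Flank-Anchored Quantification of CRISPR Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genome-editing outcomes (indel spectra, knock-in and
    base-edit allele frequencies, quality-control ratios) from directories of
    demultiplexed amplicon FASTQ files using exact-substring matching of two
    user-chosen flanking anchor sequences. Reads containing both anchors are
    classified by the length of the inter-anchor region relative to the
    wild-type reference, binned by exact sequence, and screened for user-named
    test sequences. Results are rendered as a sortable master-summary CSV and
    a top-reads TXT per run. Includes a deterministic synthetic-read simulator
    for allele mixtures with per-base substitution noise, and a command-line
    entry point for batch screening of one to thousands of samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
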