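Package: epimeet
Title: Meet-in-the-Middle Integration of Epigenome-Wide Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates summary-level hit lists from epigenome-wide
    association studies of an exposure and of an outcome through a
    meet-in-the-middle design: differentially methylated regions are
    expanded to their constituent CpG probes against an array manifest,
    per-study CpG and gene lists are harmonized across the 450K and EPIC
    platforms, cross-study overlaps are tested with one-sided
    hypergeometric tail probabilities under explicit universe-selection
    rules, and gene lists are carried into over-representation and
    pathway-level overlap analysis with Benjamini-Hochberg control.
    Includes a synthetic-data generator with planted overlap structure so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
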