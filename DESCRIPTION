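Package: dyadsub
Title: Nucleosome Dyad-Anchored Substitution Analysis and
    Nucleosome-Sequence Coevolution Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how nucleotide substitutions distribute around
    nucleosome dyads and what that implies about mutation bias, selection,
    and sequence-driven nucleosome repositioning. Provides parsimony-based
    lineage assignment of substitutions from focal/sister/outgroup
    alignments with 4-fold-degenerate-site and CpG-context classification;
    dyad-anchored, base-change-category-specific substitution-rate profiles
    with eligible-site-weighted linear trend tests and LOWESS smoothing;
    GC-based (and pluggable) nucleosome occupancy scoring with
    ancestral-versus-extant dyad offset metrics; and a forward simulator of
    nucleosome-sequence coevolution that doubles as a synthetic-data
    generator for scenario analysis (mutation bias, purifying selection on
    nucleosome position, sequence-driven repositioning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
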