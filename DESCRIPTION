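Package: famchar
Title: Gene Family Mining and Characterization from Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genome-wide characterization of a
    protein family, built around the plant ubiquitin-conjugating enzyme (E2)
    family as the worked case. Mines family members from a proteome with a
    position-specific scoring profile and Gumbel-calibrated E-values, filters
    incomplete and redundant candidates, and names members by chromosomal
    location. Computes physicochemical properties (ORF length, molecular
    weight, isoelectric point), assigns E2 architecture classes from terminal
    extensions, and flags catalytically inactive UBC-domain variants (UEVs).
    Builds neighbor-joining trees from p-distances with bootstrap supports and
    reference-guided group assignment, elicits conserved protein motifs by
    expectation maximization, scans 1.5-kb promoters for IUPAC cis-element
    consensi, and quantifies expression (FPKM, hierarchical clustering,
    permutation-based differential-expression calls, qPCR delta-Ct). Seeded
    synthetic genome, count and Ct generators provide ground-truth inputs for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
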