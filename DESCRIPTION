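Package: bfbsim
Title: Breakage-Fusion-Bridge Simulation and Repair-Product Genotyping for
    Conditional Dicentric Yeast Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of the breakage-fusion-bridge (BFB) cycle
    of a conditionally dicentric Saccharomyces cerevisiae chromosome III, in
    which a galactose-regulated centromere (GALCEN3) is placed 6.5 to 57.7 kb
    from the endogenous centromere eCEN3. The package builds annotated
    synthetic references for the six engineered configurations, simulates
    division cycles with bridge breakage and pathway-resolved repair
    (single-strand annealing, reciprocal crossover, end-joining, refusion),
    predicts diagnostic colony-PCR products from derivative karyotypes with an
    in-silico PCR engine, classifies colonies into repair classes with a
    presence/absence decision key, decomposes sequenced deletion junctions
    into deletion intervals and flanking microhomology, and aggregates
    viability and cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
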