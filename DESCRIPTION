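Package: estbridge
Title: Transitive EST-Bridge Annotation of Short cDNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates short, poor-quality cDNA clone libraries from
    taxa that are under-represented in protein databases by bridging
    through expressed sequence tags (ESTs).  Provides an exact
    affine-gap Smith-Waterman engine with Karlin-Altschul E-value
    statistics (nucleotide, translated 6x6-frame and
    protein-vs-translated modes), vector/primer contamination
    screening and trimming, a two-pass search with consensus
    filtering, translated best-hit annotation transfer with
    hierarchical category roll-up, keyword-driven enzyme-candidate
    screening with reciprocal verification, in-silico PCR, and a
    seeded synthetic-data generator that emulates a subtracted coral
    cDNA library searched against a contaminated EST collection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
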