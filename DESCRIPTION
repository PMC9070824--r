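Package: nonbscan
Title: Non-B DNA Motif Prediction and Centromere Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("nonbscan", "developers", email = "nonbscan@example.org",
           role = c("aut", "cre"))
Description: Predicts non-B-form DNA motifs (inverted repeats/dyad symmetries,
    A-phased repeats, G-quadruplexes, H-DNA, slipped-strand direct repeats,
    short tandem repeats, triplex-forming homopurine tracts, and Z-DNA) from
    genome assemblies, scores G-quadruplex propensity with a G4Hunter-style
    sliding window, and tests whether designated centromere contigs are
    enriched in these structures relative to GC- and length-matched random
    control segments.  Includes per-base likelihood tracks, ingestion of
    stress-induced structural-transition (SIST-style) probability tables,
    interpulse-duration (IPD) meta-profile validation, and a seeded synthetic
    genome generator with planted ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
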