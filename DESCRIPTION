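Package: ednaport
Title: Replicated eDNA Metabarcoding Surveys: Occupancy-Based Decontamination and Gear Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hierarchically replicated environmental DNA (eDNA)
    metabarcoding surveys paired with conventional trawl sampling. Simulates
    surveys with a station/location/bottle (+ field blank) design under a
    latent occupancy model with imperfect detection and false positives;
    ingests and validates taxa-by-sample read tables, sample metadata,
    taxonomy assignments and trawl catch tables; removes contaminant signal
    using field blanks and abundance floors; fits a two-state site-occupancy
    model with false positives to per-species replicate detection histories
    and filters detections on posterior occupancy; quantifies sampling
    completeness with incidence-based coverage, Chao2 richness and
    rarefaction/extrapolation; characterises spatial community structure via
    the eDNA index, Jaccard/Bray-Curtis dissimilarities, principal
    coordinates analysis and nested PERMANOVA; and compares eDNA detections
    against paired trawl catches through overlap categories, Venn counts and
    reference-database audit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
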