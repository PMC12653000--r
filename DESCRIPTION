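Package: tisspec
Title: Transcript-Level Tissue Specificity and Comparative Promoter Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a per-transcript, per-tissue specificity index
    (standardized deviation from the transcript's cross-tissue mean, scaled
    to [-1, 1] by max-abs normalization), assigns transcripts to enrichment
    categories, and integrates the results across two species through
    ortholog tables, disease annotations and physical-interaction networks.
    Also profiles strand-aware nucleotide composition around transcription
    start sites and exports core-promoter windows for external motif
    discovery. Ships seeded synthetic-data generators emulating two-species
    expression atlases, annotated genomes with planted promoter composition
    signals, and ortholog/interaction/disease tables, so the whole pipeline
    is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
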