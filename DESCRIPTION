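Package: prophagetools
Title: Detection, Curation and Comparative Analysis of Inducible Prophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering and characterising prophages in
    bacterial genomes from chemical-induction sequencing data. Detects actively
    replicating elements as elevated-coverage regions in read-depth profiles
    (robust per-segment background statistics, sliding-window calling, a
    plasmid copy-number rule, and hierarchical border refinement from clipped
    reads, coverage steps or gene spans), curates candidates by viral gene
    content and assigns viral realms, quantifies induction as a phage-to-host
    coverage ratio, finds recently transferred prophage pairs by fragment-based
    average nucleotide identity, clusters prophage proteins into gene families
    by Markov Clustering, and extracts variable (accessory) gene loci from
    prophage clusters. Includes a seeded synthetic-data generator that emulates
    the statistical structure of induction sequencing so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
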