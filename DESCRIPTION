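Package: olspr
Title: Multi-Primer COI Metabarcoding with Control-Calibrated Noise Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A variant-centred (clustering-free) workflow for diet
    metabarcoding with several overlapping primer sets on one locus
    (the 5' COI barcode). Demultiplexes merged tagged amplicon reads,
    dereplicates them into exact sequence variants, removes
    low-frequency noise with thresholds calibrated on mock and negative
    controls, screens PCR replicates by Renkonen distance, enforces a
    minimum-replicate rule, merges variants from different primer sets
    into contigs over their identical overlap, clusters validated items
    into MOTUs by 3% complete-linkage, assigns taxonomy by the lowest
    taxonomic group approach, and computes coverage, complementarity,
    dissimilarity and resolution statistics. Includes a synthetic-run
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    vctrs,
    withr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
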