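Package: picluster
Title: Comparative Discovery and Evolution of piRNA Cluster Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls genic and intergenic piRNA cluster (piC) loci from
    strand-specific small-RNA coverage, scores their single-stranded
    configuration, compares piC and mRNA expression repertoires across
    species rooted by gene orthology, classifies Eutherian-conserved
    loci, and estimates gain/loss rates on a dated phylogeny by Wagner
    parsimony. Ships a synthetic-data generator emulating strand-specific
    small-RNA sequencing libraries so every stage is testable end to end
    with known ground truth. All user-facing functions take and return
    tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
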