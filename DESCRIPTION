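Package: palaeomito
Title: Ancient Mitochondrial Genome Assembly, Authentication and Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and authenticating ancient human
    mitochondrial genomes from short damaged sequencing reads. Provides a
    seeded simulator of ancient-DNA read data (log-normal fragment lengths,
    terminal cytosine-deamination damage, Phred-conditioned sequencing error,
    modern-human contamination), an iterative reference-guided circular
    assembler with unique-molecule collapsing and quality-argmax consensus
    calling, substitution-frequency damage profiling by distance from the
    fragment ends, contamination estimation from diagnostic positions with
    Wilson score bounds, and hotspot-masked haplogroup classification,
    private-variant arithmetic and neighbor-joining tree building. All
    user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
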