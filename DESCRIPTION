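Package: bioflink
Title: Virus-Prokaryote Interaction Analysis for Marine Biofilm Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for virus-prokaryote interaction analysis in
    assembled biofilm metagenomes: triage of viral scaffolds into proviruses,
    closed genomes (direct-terminal-repeat rules), bins and fragments;
    four-channel virus-host linkage (sequence homology, CRISPR spacers,
    shared tRNA genes, shared 25-mers); fragment-based average nucleotide
    identity and 95 percent population clustering; coverage and
    virus-to-prokaryote ratios; RPKM/TPM quantification with a binary
    expression rule; rule-based calling of anti-viral defence systems,
    viral counter-defence genes and auxiliary metabolic genes; and
    biofilm-versus-seawater differential abundance with a
    DerSimonian-Laird random-effects meta-analysis across locations.
    Ships a synthetic-community generator with planted ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    igraph,
    MASS,
    yaml,
    jsonlite,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    DESeq2,
    Rsamtools,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
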