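Package: equimhc
Title: Diversity and Selection Analysis of MHC Class II Exon 2 Sequences in Equids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for analysing major histocompatibility complex
    (MHC) class II DRB/DQB exon 2 sequence diversity and selection in the
    horse family: gene presence/absence calls from per-base coverage,
    allele calling from tagged amplicon reads, alignment diversity indices
    and trans-species allele sharing, codon-based dN/dS selection tests
    (a global Z-test plus counting- and likelihood-based site-wise methods
    with a two-method consensus rule), and a single-breakpoint
    recombination screen using the small-sample Akaike information
    criterion. Includes seeded simulators for codon alignments with
    site-class-specific omega, decorated amplicon reads and depth tracks,
    so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
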