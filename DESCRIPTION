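Package: selscreen
Title: Selective Multi-Target Screening of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies organism-selective, multi-target antimicrobial
    candidates from constraint-based metabolic models. Enumerates single
    essential reactions and minimal synthetic lethal reaction sets (orders
    one to four) under a rich, aerobic medium using a depth-first search
    with flux-support pruning, then screens every targeted/conserved
    organism combination: a candidate set must abolish growth in all
    targeted organisms in their most resilient state and leave every
    conserved organism viable in its most vulnerable (minimal medium, low
    oxygen) state. Includes a built-in flux balance analysis solver,
    readers for BiGG-style JSON and SBML Level 3 FBC models, pathway
    participation reports, greedy key-reaction coverage collections, and a
    synthetic-model generator with planted, provable lethality structure
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    Matrix,
    xml2,
    yaml,
    utils,
    stats
Suggests:
    pracma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
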