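Package: inadnet
Title: Carbon-Backbone Network Annotation from 2D INADEQUATE and JRES NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates metabolite carbon backbones from 2D 13C INADEQUATE
    spectra. Picks peaks with a multi-threshold ladder, assembles
    carbon-backbone networks from double-quantum symmetry rules, matches
    networks against a simulated compound database built from assigned 13C
    chemical shifts and bond structure, and transfers compound annotations
    to 1D 13C-JRES projection peaks. Ships a forward simulator for
    INADEQUATE and JRES spectra so every stage can be validated against
    known ground truth, plus a step-wise pipeline with checkpointing and
    reproducible report files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
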