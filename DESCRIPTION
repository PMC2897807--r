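Package: msatmap
Title: Duplication-Aware Alignment and Evolutionary Analysis of Minisatellite Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing minisatellite maps (sequences of repeat-unit
    type symbols produced by MVR-PCR typing) under an explicit model of map
    evolution with unit mutation, tandem single-copy duplication, insertion and
    deletion.  Provides minimum-cost duplication-history reconstruction,
    optimal pairwise map alignment in which unmatched runs are explained as
    duplication offspring of flanking inherited units or as indels, an optional
    double-copy (periodic "xyxy") extension, BIONJ phylogeny construction from
    all pairwise alignment costs, scramble (randomization) tests for polar
    structural variation via pivot points and for directional duplication bias
    via restricted-direction alignment counts, a map evolution simulator for
    parameter-recovery verification, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
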