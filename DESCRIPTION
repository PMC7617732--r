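Package: crossreact
Title: Simulation and Analysis of Cross-Reactive Antibody Display Selections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering broadly cross-reactive antibodies from
    display-selection campaigns analysed by deep sequencing (sort-seq).
    Includes a generative simulator of multi-round magnetic and
    fluorescence-activated sorting with a Langmuir occupancy binding law and
    planted ground truth; enrichment calling and cross-reactivity
    deconvolution across parallel antigen sorts; repertoire analytics (gene
    usage, CDRH3 length distributions, position frequency matrices, Shannon
    entropy, motif scanning, substitution enrichment); antigen-side breadth
    classification of displayed toxin variant libraries (binding, escape,
    dysfunctional); neighbor-joining phylogenetics with Jukes-Cantor
    distances; and Kaplan-Meier and Mantel-Cox log-rank survival statistics
    for in vivo protection readouts.
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
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
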