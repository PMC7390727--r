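Package: pentacensus
Title: Census of C-Terminal Pentapeptides in Bacterial Chemoreceptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect the C-terminal CheR/CheB-binding pentapeptide
    (pattern xZxxZ, Z in {F, W, Y}; archetype NWETF) on methyl-accepting
    chemotaxis proteins, classify receptors by membrane topology,
    ligand-binding-domain family and domain architecture, aggregate
    pentapeptide abundance across genomes, taxa, habitats and receptor
    families, and summarise the pentapeptide alphabet as a position weight
    matrix with information content, consensus and net-charge statistics.
    Includes a synthetic proteome generator with known ground truth for
    validating every stage of the census at desk scale.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
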