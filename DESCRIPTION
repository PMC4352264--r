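Package: ccchfam
Title: CCCH Zinc-Finger Gene Family Characterization Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-scale characterization of CCCH-type
    zinc-finger (C3H) gene families in plants: degenerate C-X(i)-C-X(j)-C-X3-H
    motif scanning and tallying, sequence-logo position profiles, molecular
    weight and isoelectric point computation, p-distance neighbor-joining
    phylogenetics with bootstrap support and clade calling, tandem/homeologous
    duplication typing from chromosomal loci, Nei-Gojobori Ka/Ks estimation
    with Jukes-Cantor correction, selection-mode classification and
    molecular-clock divergence dating, strand-aware IUPAC cis-element promoter
    scanning, expression-atlas normalization and hierarchical clustering, and
    delta-delta-Ct qRT-PCR quantification. Seeded synthetic-data generators
    make every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
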