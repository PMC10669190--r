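Package: contactdof
Title: Contact-Based Analysis of Disordered Peptide Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses conformational ensembles of short capped peptides, such as
    ligand-modified segments of the androgen receptor activation function 1
    region, through residue-residue contact statistics. Provides a synthetic
    helix-coil ensemble generator with an optional fragment-labelled
    pseudo-ligand, multi-model PDB input/output, any-atom distance-cutoff
    contact maps and their upper-triangle contact degree-of-freedom vectors,
    Kabsch-Sander eight-state secondary-structure assignment with per-residue
    state fractions, fragment-resolved protein-ligand contact profiles, and
    linear (PCA) plus nonlinear low-dimensional embeddings of contact vectors,
    together with a config-driven pipeline that runs the full analysis per
    system and across systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
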