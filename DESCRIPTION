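Package: ffdat
Title: Relational Data Scheme and Typing Engine for Transferable Force Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the TUK-FFDat data scheme for transferable classical
    force fields: a four-part tag notation identifying interaction-site types,
    a registry of intermolecular and intramolecular potential functions
    (Lennard-Jones, Mie, harmonic bonds and angles, cosine-series torsions,
    improper torsions, scaled 1,n interactions and special pair potentials),
    and the seven-section relational data format holding a transferable force
    field as tables of tag tuples, potential identifiers and parameters.
    Datasets round-trip between tibbles, SQLite databases and spreadsheet
    workbooks.  A molecular-graph typing engine fuses hydrogens into
    united-atom sites, assigns functional groups and derives tags, and an
    assembler enumerates bonded terms on the site graph, resolves each against
    a dataset with wildcard and specificity semantics, and evaluates
    component-specific energies on coordinates.  The TraPPE-UA alkane and
    alcohol parameter set is bundled as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    igraph,
    jsonlite,
    readxl,
    DBI,
    RSQLite,
    generics,
    ggplot2,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
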