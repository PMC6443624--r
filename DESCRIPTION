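Package: domtol
Title: Building, Rooting and Auditing Trees of Life from Protein Domain Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenomic analysis of genomic censuses of protein
    structural domains (SCOP fold superfamilies, FSFs). Raw FSF abundance
    counts per proteome are coded into multistate characters on a 32-symbol
    ordered alphabet, scored under Fitch (unordered), Wagner (ordered) and
    generalized Sankoff stepmatrix parsimony, and assembled into trees of life
    that are rooted a posteriori by attaching hypothetical ancestors
    (Lundberg optimization under Weston's generality criterion) or
    intrinsically by asymmetric stepmatrices. The package audits
    character-transformation models empirically: ancestor sweeps relating
    retention index to tree length, character-state reconstruction and
    change-frequency matrices, frequency-derived (Wheeler) stepmatrices with a
    dynamic-weighting refinement round, triangle-inequality audits, and rooted
    tree distances (hardwired cluster and hybridization numbers via agreement
    forests). A birth-death simulator of proteome domain content with rare
    innovation provides fully reproducible synthetic datasets for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
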