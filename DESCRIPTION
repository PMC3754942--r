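Package: alphareplib
Title: Combinatorial Repeat-Protein Library Design and Binding-Model Toolkit
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and quality control of combinatorial libraries of artificial
    helicoidal repeat proteins (alphaRep). Expands IUPAC degenerate codons,
    computes residue distributions of weighted codon-cassette mixtures, builds
    position-specific and dipeptide profiles from aligned repeat collections
    (with a synthetic-collection generator), selects budget-limited degenerate
    cassette sets by greedy maximum coverage with swap refinement, fits cassette
    mixing weights on the probability simplex, accounts exactly for encoded
    sequence space and library sampling coverage, simulates micro-gene
    circle-assembly libraries with frame-shift errors plus phage-display
    filtration and module shuffling, annotates clone sequences against a
    configurable scaffold, and simulates and fits the biophysical binding
    models used to characterise selected binders (one-site and competitive
    displacement isothermal titration calorimetry, two-state differential
    scanning calorimetry, 1:1 surface plasmon resonance kinetics).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
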