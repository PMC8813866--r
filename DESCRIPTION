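Package: dpfold
Title: Component-Based Dynamic Programming Engines for RNA Secondary
    Structure Prediction
Version: 0.1.0
Authors@R:
    person("dpfold", "developers", email = "dpfold@example.org",
           role = c("aut", "cre"))
Description: A single coherent toolkit for pseudoknot-free RNA secondary
    structure prediction built around one generic dynamic-programming
    engine contract. Four pluggable folding strategies share the engine:
    maximum base pairing (Nussinov), minimum free energy over a
    loop-decomposition energy model (Zuker), helix/stem-region folding
    over an enumerated stem pool, and a Boltzmann-ensemble partition
    function with base-pair probabilities. Includes readers and writers
    for FASTA, dot-bracket and CT formats, base-pair-level
    sensitivity/specificity/Matthews-correlation evaluation, seeded
    synthetic sequence generation, exhaustive structure enumeration
    oracles for testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
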