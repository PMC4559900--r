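Package: coevdock
Title: Coevolution-Driven Docking of Homodimeric Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts homodimeric protein complexes from sequence
    coevolution. Infers directly coupled residue pairs from a protein
    family alignment by mean-field direct coupling analysis (mfDCA),
    isolates dimerization signals by filtering out buried and monomeric
    couplings, and uses the surviving pairs as Gaussian-well restraints
    in a coarse-grained C-alpha structure-based model. A staged Langevin
    annealing protocol docks two monomer copies into a complex, which is
    scored against a reference by dimer RMSD and interfacial RMSD. A
    synthetic-data module provides Potts-sampled alignments with planted
    couplings and toy dimer structures so the whole pipeline can be
    exercised without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
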