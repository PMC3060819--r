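Package: pbrefine
Title: Protein Block Refinement of Structurally Variable Regions in
    Pairwise Structure Alignments
Version: 0.1.0
Authors@R:
    person("PB", "Refine Developers", email = "pbrefine@example.org",
           role = c("aut", "cre"))
Description: Encodes protein backbones as the 16-letter Protein Block (PB)
    structural alphabet, detects structurally conserved (SCR) and variable
    (SVR) regions in a rigid-body superposition of two homologous chains,
    re-aligns the PB strings of each variable region with an affine-gap
    dynamic program under a PB substitution matrix, and scores, classifies
    and reports the local conformational similarity that a global
    superposition obscures.  Includes a synthetic-backbone generator
    (dihedral prototypes to Cartesian coordinates) so the whole pipeline is
    testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
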