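Package: elongsim
Title: Stochastic Diffusion-Collision Simulation of Translation Elongation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice-based Gillespie simulation of diffusion-limited translation
    elongation in Escherichia coli. Ternary complexes (EFTu-GTP-aminoacyl-tRNA)
    perform a random walk on a periodic 3-D lattice and elongate fixed ribosomes
    on cognate collisions, subject to a catalytic refractory time and first-order
    complex dissociation. Includes bundled in vivo parameter tables (ribosome,
    EFTu and per-species tRNA copy numbers at growth rate 1.1 per hour), a
    synthetic codon-sequence generator with tunable adaptation to the tRNA pool,
    elongation-rate estimation with replicate errors and slope comparison,
    metabolic control analysis (substrate elasticity and ribosome flux control
    coefficient by central finite differences), and ATP-budget allocation across
    tRNA, EFTu and ribosome synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
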