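Package: epidom
Title: Thermodynamic Models of Epistasis and Dominance in Diploid Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium thermodynamic genotype-phenotype models for a single
    diploid gene: a two-state (unfolded/folded) protein folding model and a
    three-state model adding one-to-one ligand binding under mass conservation.
    On top of the models the package quantifies within-allele genetic
    interactions (intra-molecular epistasis), between-allele interactions and
    the degree of dominance of compound heterozygotes, using both additive and
    log-additive null expectations, optionally through nonlinear (concave,
    convex, sigmoidal) concentration-phenotype linking functions. Includes
    deterministic mutation-grid scenario sweeps, phenotype-to-energy inversion,
    a flow-cytometry scoring stage (scatter gating, GFP normalization and exact
    standard-error propagation) and a synthetic event generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
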