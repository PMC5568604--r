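Package: cgdock
Title: Coarse-Grained Protein-Peptide Docking with Replica-Exchange Monte
    Carlo and Contact-Driven Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained engine for flexible protein-peptide docking in
    a CABS-style coarse-grained representation: each residue is reduced to
    alpha-carbon, beta-carbon and side-chain pseudoatoms plus a peptide-bond
    center, with the alpha-carbon trace restricted to a cubic lattice.
    Peptide copies are scattered around the receptor and docked by
    replica-exchange Metropolis Monte Carlo under a surrogate statistical
    force field, optionally biased toward the binding site by a soft
    one-sided linear restraint on chosen side-chain contact distances; the
    restraint steers sampling but is excluded from the scoring energy.  The
    resulting model pool is reduced to ten ranked predictions by an energy
    filter, k-medoid clustering on ligand RMSD, and cluster-density ranking.
    Includes a generator of synthetic pocket-bearing toy complexes with
    known native poses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
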