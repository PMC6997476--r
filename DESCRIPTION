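Package: torsconf
Title: Combined Systematic-Stochastic Torsional Conformer Search and
    Multi-Structural Partition Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the torsional conformers of flexible acyclic molecules by
    combining a preconditioned systematic enumeration of dihedral angles with a
    Monte Carlo search that excludes hypercubes around previously visited points
    of the torsional space.  Guess and optimized geometries are screened by
    connectivity, similarity, redundancy and Hessian tests; conformational
    enantiomers are generated rather than re-optimized.  The located ensemble
    feeds multi-structural rovibrational partition functions (MS-HO, MS-QH and
    the coupled torsional MS-T framework), conformer populations and Gibbs free
    energies over a temperature grid.  Includes Gaussian-style Z-matrix input,
    analytic chain-molecule model potentials with quasi-Newton optimization and
    finite-difference Hessians, an adapter contract for external
    electronic-structure programs, XYZ/TSV/CSV writers and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
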