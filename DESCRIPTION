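Package: saptvqe
Title: First-Order Symmetry-Adapted Perturbation Theory from Active-Space
    Quantum-Eigensolver Density Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes first-order intermolecular interaction energies
    (electrostatics and S^2-approximate exchange) between two closed-shell
    monomers by symmetry-adapted perturbation theory, using the spin-summed
    one- and two-particle reduced density matrices of active-space monomer
    wavefunctions.  Monomer wavefunctions may be restricted Hartree-Fock,
    exact active-space configuration interaction (CASCI), or an ideal
    statevector simulation of a layered unitary cluster-Jastrow (k-muCJ)
    variational quantum eigensolver under the Jordan-Wigner encoding.
    Includes a self-contained Gaussian integrals engine (McMurchie-Davidson,
    s/p/d Cartesian shells), restricted Hartree-Fock with DIIS, active-space
    embedding with core folding, a measurement-basis optimization that
    evaluates the electrostatic energy in a single commuting group of
    occupation-number expectations, and deterministic benchmark fixtures
    (water dimer with a stretched donor, T-shaped benzene/p-benzyne dimer,
    small H2-H2 and He-He test systems).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
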