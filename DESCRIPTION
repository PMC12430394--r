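Package: itacorr
Title: Information-Theoretic Density Descriptors and Correlation-Energy
    Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes eleven information-theoretic descriptors of the
    electron density (Shannon entropy, Fisher information,
    Ghosh-Berkowitz-Parr entropy, Onicescu information energies, relative
    Renyi integrals, information gain, and three relative Fisher
    information measures summed over Hirshfeld atoms) by multicenter
    numerical integration over promolecular or wavefunction-backed
    densities.  Fits and applies single-descriptor linear models that
    predict post-Hartree-Fock electron correlation energies at
    Hartree-Fock cost (the LR(ITA) protocol), and assembles large-cluster
    energies with the generalized energy-based fragmentation (GEBF)
    inclusion-exclusion scheme.  Ships transcriptions of published
    descriptor/energy benchmark tables for polymers and molecular
    clusters, plus synthetic Gaussian-atom fixture generators with
    closed-form reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
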