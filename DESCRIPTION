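Package: xtalpath
Title: Crystal Polymorph Search in the NPT Ensemble via an Alchemical
    Vacuum-Crystal Path
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organic crystal structure prediction by direct
    sampling of the isothermal-isobaric (NPT) ensemble along an alchemical
    deposition/sublimation path. A coupling parameter lambda connects an
    isolated vacuum molecule (lambda = 0) to the fully interacting crystal
    (lambda = 1); sampling is accelerated with an orthogonal space tempering
    bias deposited over (lambda, dU/dlambda), pressure is controlled by a
    Monte Carlo barostat that preserves lattice-system constraints, and
    energies are evaluated on the space-group asymmetric unit with a
    surrogate pairwise force field (buffered 14-7 van der Waals with
    alchemical softcore, damped shifted-force point-charge electrostatics,
    harmonic bonded terms). Includes local crystal minimization, energy and
    density filtering, rmsd_N crystal packing comparison with Kabsch
    superposition, iterative minimum-cluster-count clustering, deterministic
    toy fixtures, and readers/writers for extended XYZ, CIF, parameter and
    configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
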