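Package: vibflow
Title: Variational Vibrational Spectra in Normalizing-Flow Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational calculation of vibrational (and general
    few-dimensional Schroedinger) eigenstates in direct-product bases
    evaluated in learned coordinates. An invertible, domain-bounded residual
    flow composed with orthonormal primitive bases (Hermite, Legendre with a
    sin^1/2 factor) yields an augmented basis that stays orthonormal for any
    flow parameters; matrix elements of the curvilinear kinetic-energy
    operator (Wilson G-matrix plus Podolsky pseudopotential), the potential,
    and the overlap are assembled by Gaussian quadrature, and the flow
    parameters are trained by gradient descent on variational losses (trace
    of the Hamiltonian or a sum of the lowest eigenvalues). Includes polyad
    basis truncation, projection-based quantum-number assignment onto
    contracted one-dimensional eigenfunctions, basis-set convergence-rate
    fitting, transferability of trained coordinates across truncation levels,
    analytic model systems with independent reference spectra, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
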