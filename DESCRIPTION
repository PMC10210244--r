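Package: hhpfmd
Title: Hamiltonian Hybrid Particle-Field Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A serial simulator for Hamiltonian hybrid particle-field (HhPF)
    molecular dynamics of coarse-grained soft matter. Particle number densities
    are assigned to a mesh by cloud-in-cell interpolation and smeared by a
    grid-independent Gaussian filter in reciprocal space, so that field forces
    are exact gradients of the interaction energy functional and converge
    systematically under grid refinement. Includes reciprocal-space (smeared
    particle-mesh Ewald) electrostatics, coarse-grained bonded mechanics with a
    combined bending-torsional backbone potential and topological dipole
    reconstruction, a time-reversible rRESPA multiple-time-step integrator with
    a canonical sampling velocity rescaling (CSVR) thermostat, deterministic
    fixture builders, trajectory output in an H5MD-style layout, and analysis
    tools (filter-width calibration, density profiles, energy drift, periodic
    density-based clustering, bilayer detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
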