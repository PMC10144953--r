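Package: dpdlipid
Title: Dissipative Particle Dynamics of Lipid-Nanoparticle Melts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained dissipative particle dynamics (DPD) engine and
    analysis toolkit for amphiphilic lipid melts loaded with single-bead
    nanoparticles. Builds random, lamellar and hexagonal starting
    configurations of head-tail lipid chains, integrates the DPD equations of
    motion with the Groot-Warren modified velocity-Verlet scheme under
    periodic boundaries, and computes the standard structural and mechanical
    observables of mesophase self-assembly: axial and radial density
    profiles, the P2 orientational order parameter, gyration-tensor
    components, and Irving-Kirkwood pressure tensors with slab-resolved
    interfacial-tension profiles. Includes synthetic fixtures with analytic
    expectations, LAMMPS data/dump and extended-XYZ writers, and a YAML-driven
    experiment orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
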