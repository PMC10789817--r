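Package: rodnet
Title: Transport of Thick Rodlike Particles in Cross-Linked Macromolecular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissipative particle dynamics (DPD) simulation and theory of the
    transport of rigid rodlike particles whose diameter is comparable to the
    mesh size of a cross-linked macromolecular network. Provides a
    Groot-Warren DPD engine with a quaternion rigid-body integrator, builders
    for hexa-functional (simple-cubic) networks with controllable mesh-size
    polydispersity and for volume-filled bead rods, trajectory observables
    (axial displacement, mean squared displacement, van Hove self-correlation,
    non-Gaussian parameter, wavelet-based hop detection) with a
    Brownian/sliding/hopping/trapped regime classifier, Gaussian-bridge Monte
    Carlo evaluation of the rod-network entropic free-energy landscape with
    the k_BT barrier criterion and its phase diagram, and closed-form
    continuous-time random-walk displacement distributions for the three
    dynamical regimes together with Montroll-Weiss utilities, a periodic-
    potential Fokker-Planck solver and a seeded trajectory sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
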