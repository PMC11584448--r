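Package: mammotion
Title: Multi-Component Finite-Element Simulation of Breast Biomechanics
    During Running
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating the dynamic mechanical response of the
    female breast during running with a multi-component nonlinear
    finite-element model.  The package generates a parametric synthetic
    anatomy (subcutaneous soft-tissue layer, adipose tissue, pectoralis
    major, Cooper's ligament network, glandular lobes and ducts, and a
    skin membrane) meshed with conforming linear tetrahedra, assigns
    nearly incompressible hyperelastic materials (Neo-Hookean and
    five-parameter Mooney-Rivlin), solves quasi-static gravity loading
    and implicit Newmark transient dynamics with prescribed torso motion,
    recovers the gravity-free reference configuration by fixed-point
    inverse iteration, and provides validation metrics (zero-lag
    Butterworth filtering, relative mean absolute error of key-point
    trajectories, and nearest point-to-triangle surface-to-surface
    distance) together with regional stress summaries and internal
    stiffness sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    xml2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
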