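Package: ecgfwd
Title: Forward ECG Simulation and Cardiac Source Sampling Analysis
Version: 0.1.0
Authors@R:
    person("ECG Forward", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to study how incomplete sampling of cardiac surface
    potentials degrades the electrocardiographic forward solution. Provides
    triangulated surface mesh handling (pts/fac, OFF and ASCII PLY dialects)
    with ellipsoidal-cap closure of open sock-like meshes, synthetic
    heart-in-torso scenes driven by moving current dipoles, Laplacian
    interpolation of unsampled surface potentials, a boundary element method
    (BEM) transfer matrix from pericardial to body-surface potentials with
    analytically integrated linear collocation elements, the incremental
    atrial sampling strategies (AV-plane first, roof first, combined,
    uniform, random), plaque clusters and basal-ventricular removal, the
    standard error metrics (RMS error, relative RMS error, uncentered
    correlation), and a pipeline runner that reproduces the full
    sampling-ablation experiment on synthetic scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
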