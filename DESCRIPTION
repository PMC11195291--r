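Package: logprf
Title: Log-Bar Population Receptive Field Mapping
Version: 0.1.0
Authors@R:
    person("logprf", "developers", email = "logprf@example.org", role = c("aut", "cre"))
Description: Tools for population receptive field (pRF) mapping with a
    logarithmically warped drifting-bar stimulus. Generates fixed-bar and
    log-bar aperture movies (eccentricity warp r' = c*log(1 + k*r)), models
    voxel responses as an isometric 2-D Gaussian pRF whose stimulus overlap
    is convolved with a six-parameter double-gamma hemodynamic response
    function, fits pRFs by coarse grid search followed by derivative-free
    simplex refinement with alternating HRF estimation, and reproduces the
    parameter-recovery simulations that quantify the accuracy advantage of
    the log-bar stimulus for small foveal pRFs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
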