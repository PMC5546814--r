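Package: spiralscope
Title: Attractor Identification in Neural Population Spike-Train Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and characterises low-dimensional periodic attractors in
    population spike-train recordings, as found in fictive locomotion of the
    Aplysia pedal ganglion. Converts spike trains to Gaussian spike-density
    functions, embeds the population with principal components, detects
    periodic orbits by recurrence analysis, tests manifold convergence and
    perturbation return with Hausdorff distances against shuffled-projection
    controls, estimates attractor parameters (orbital period, contraction
    rate, stable/unstable spiral classification) from local linear models of
    the trajectory, decodes motor-nerve output with a log-link history GLM,
    and quantifies single-neuron participation with an outlier noise model.
    Ships a synthetic-data suite (Matsuoka mutual-inhibition oscillator,
    latent decaying-spiral populations with known ground truth, phase-locked
    nerve output) for validation against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
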