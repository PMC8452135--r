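Package: mepmap
Title: Gaussian-Process Active Sampling for TMS Motor-Cortex Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation toolkit for automated transcranial
    magnetic stimulation (TMS) motor mapping. Models the spatial field of
    motor-evoked-potential (MEP) amplitudes with Gaussian-process (GP)
    regression and a square-root warped GP that guarantees non-negative
    field estimates; provides entropy- and mutual-information-based
    acquisition criteria (GPE, amplitude-space GPE, warped-GP entropy),
    a greedy entropy-driven sampling loop, an adaptive random sampler
    that draws stimulation loci from the normalized warped-GP mean by
    accept-reject, and uniform grid/random baselines. Includes synthetic
    excitability-field generators, ground-truth surrogate construction
    from recorded MEP samples, standard motor-map metrics (normalized
    mean squared error, map volume and area by double trapezoidal
    integration, center of gravity), and reproducible run configuration
    with JSON manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
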