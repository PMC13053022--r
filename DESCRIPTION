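Package: metasearch
Title: Resource-Rational Simulation of Immersive Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates visual search in cluttered three-dimensional scenes as a
    meta-level Markov decision process whose states are Gaussian beliefs over
    object features and whose actions are fixations. Provides a synthetic scene
    generator, foveated measurement sampling with Bayesian cue combination, the
    target posterior and the Fixate-MAP policy with threshold optimization,
    explicit (D2 shape, CIE L*a*b* color) and implicit (pooled embedding)
    feature-space construction with PCA reduction, a reduced-scale actor-critic
    trainer demonstrating convergence to Fixate-MAP, and metrics for comparing
    simulated and recorded gaze (relative looking times, cross-entropy with a
    lapse rate, transition-matrix Mantel tests, reaction-time mapping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    withr,
    yaml
Suggests:
    EBImage,
    vegan,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
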