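Package: boubakit
Title: Radial-Frequency Shapes and Sound-Shape Correspondence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying the Bouba/Kiki sound-shape correspondence
    with radial frequency (RF) patterns. Generates and renders RF contour
    stimuli whose frequency, amplitude and spikiness vary factorially;
    simulates two-alternative forced-choice responses from a logistic model
    with participant random intercepts and group-difference slopes; builds
    per-condition chi-square agreement maps; fits logistic mixed-effects
    models by maximum likelihood with Wald and parametric-bootstrap
    inference; and compares pooled versus group-specific model ladders by
    likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    lme4,
    png,
    rlang,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
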