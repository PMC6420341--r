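Package: psyadapt
Title: Adaptive Psychophysics and Aftereffect Analysis for Face-Body
    Integration Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-alternative forced-choice adaptation experiments
    on facial expression perception in body context. Implements the Psi
    adaptive procedure (expected-entropy minimisation over a PSE-by-slope
    grid), maximum-likelihood fitting of cumulative-Gaussian psychometric
    functions with fixed guess and lapse rates, parametric-bootstrap deviance
    goodness-of-fit screening, aftereffect (PSE shift) scores, signal-
    detection categorisation bias indices from confusion tables, and
    group-level frequentist and Bayesian statistics (Hedges' g, within-
    subject 2x2 ANOVA contrasts, directional JZS Bayes factors with prior
    robustness sweeps, Bayesian Pearson correlations). Includes a synthetic-
    observer generator implementing competing early- and late-integration
    hypotheses of face-body processing, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
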