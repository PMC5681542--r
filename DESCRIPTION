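Package: cephnet
Title: Gaussian Bayesian Networks for Longitudinal Craniofacial Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the rate of change of cephalometric features in growing
    Class III malocclusion patients with linear-Gaussian Bayesian networks.
    Provides two-visit cohort ingestion and atlas adjustment, difference
    (rate-of-change) variables, thresholded Pearson correlation networks,
    constrained BIC hill-climbing structure learning with whitelists and
    blacklists, ordinary-least-squares parameter learning, bootstrap model
    averaging with arc strengths and a data-driven inclusion threshold,
    forward (logic) sampling and exact Gaussian conditioning for conditional
    probability queries, do-style interventions by graph mutilation, 10-fold
    cross-validated predictive correlation and prognosis classification
    error, a scripted clinical hypothesis suite, and a synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
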