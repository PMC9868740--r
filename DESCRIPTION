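Package: gannorm
Title: Normative Modeling of Functional Connectivity with Adversarially
    Trained Discriminators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Normative ("one-class") modeling of resting-state functional
    connectivity. Generative adversarial networks are trained on
    ROI-to-ROI connectivity features from neurotypical subjects only, one
    model per resting-state brain functional network; the discriminator's
    sigmoid output is read as a per-subject neurotypicality score.
    Per-network models are combined into ensembles by mean score or
    majority vote to flag neuroatypical subjects, classification
    performance is assessed with permutation tests of balanced accuracy,
    and local surrogate (LIME-style) explanations of the discriminators
    are aggregated into per-ROI centrality maps. Includes a seeded
    simulator of block-structured connectivity cohorts with hub
    perturbations for end-to-end testing without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
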