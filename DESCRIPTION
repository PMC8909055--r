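Package: protonMBS
Title: Model-Based Selection of Proton Therapy Candidates from Paired
    Photon/Proton Dose-Volume Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico comparison of rival photon (VMAT) and proton
    (IMPT) treatment plans for head-and-neck radiotherapy. Computes dose-volume
    histogram quantifiers (Dx%, mean dose, conformity and homogeneity indices,
    integral dose), evaluates a configurable registry of normal tissue
    complication probability (NTCP) models (Lyman-Kutcher-Burman probit,
    multivariable logistic, log-logistic) on each plan, derives per-endpoint
    photon-minus-proton NTCP differences, scores patients with a weighted
    comprehensive toxicity score, and classifies proton-therapy eligibility
    with single-endpoint and composite model-based selection thresholds.
    Includes paired nonparametric cohort statistics with an auditable exact
    Wilcoxon signed-rank branch, stratified passing-rate tables, and a seeded
    generator of paired synthetic cohorts for end-to-end testing and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
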