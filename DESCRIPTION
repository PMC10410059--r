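Package: psen1traj
Title: Trajectory Divergence Modelling for PSEN1 Variant-Domain Groups in
    Autosomal-Dominant Alzheimer Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether the protein domain struck by a PSEN1
    pathogenic variant (transmembrane versus cytoplasmic) modifies clinical,
    cognitive and biomarker trajectories across expected years to symptom
    onset (EYO) in autosomal-dominant Alzheimer disease. Provides a synthetic
    cohort simulator with known ground truth, variant-to-domain
    classification, analysis-table assembly (intracranial-volume adjustment,
    composite amyloid PET SUVR), restricted-cubic-spline linear mixed-effects
    models with group-by-EYO interactions and a family random intercept,
    credible-interval divergence-point estimation from posterior draws of the
    fixed effects, mediation analysis with bootstrap indirect effects,
    per-subject annualized slope extraction with group comparison, and
    demographics and model reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    lme4,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
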