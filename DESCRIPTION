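Package: tefuse
Title: Multi-Modal Temporal Fusion of Anatomical MRI, Hyperpolarized 13C
    Spectroscopy and NMR Metabolomics for Preclinical Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a multi-modal temporal deep-learning pipeline for
    longitudinal patient-derived-xenograft (PDX) glioblastoma studies in
    mice: three-plane 3D convolutional encoders for segmented T2-weighted
    tumor volumes, a time-elapsed self/cross-view attention fusion, a 2D
    CNN plus recurrent encoder for dynamic hyperpolarized 13C pyruvate
    spectroscopy (HPMRS), a masked recurrent branch for ex vivo NMR
    metabolite panels with cohort-mean imputation, and a class-weighted
    binary classifier evaluated by repeated stratified k-fold
    cross-validation (AUROC, AUPRC and per-cohort confusion rates).
    Includes the outcome-label rules for tumor progression, radiotherapy
    treatment effect and biomarker abnormality, and a seeded synthetic
    cohort simulator (exponential tumor growth, two-site
    pyruvate-to-lactate exchange kinetics, ellipsoidal plane volumes,
    metabolite panels and experiment-driven missingness) so the whole
    pipeline runs end-to-end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
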