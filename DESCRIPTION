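Package: wmhdyn
Title: Dynamic White Matter Hyperintensity Progression Volumetrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the dynamic progression of white matter
    hyperintensities (WMH) from serial structural MRI. Baseline and
    follow-up T1 volumes are rigidly aligned into a subject-specific
    halfway ("intermediate") space via the rigid square root of the
    between-scan transform; binary WMH masks are carried into that space
    and decomposed into spatially shrinking, growing, and stable lesion
    compartments, with voxels engulfed by ventricular expansion masked
    out and tallied separately. Also provides tissue-volume bookkeeping
    (total intracranial capacity, brain parenchymal fraction), small
    vessel disease group classification, cohort summaries, and a
    synthetic longitudinal brain-phantom generator with exact
    ground-truth lesion dynamics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
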