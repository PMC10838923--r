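Package: cbident
Title: Connectome-Based Identification of Parent-Child Dyads from
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies biological parent-child dyads from functional
    connectivity (FC) profiles. Implements fingerprint-style
    identification between index-aligned sets of whole-brain FC
    profiles, a connectome-based identification (CBI) model with
    cross-group edgewise Spearman feature selection and positive and
    negative sub-models, label- and feature-level permutation tests,
    network-to-network feature contribution accounting, and
    diffusion-map embeddings of connectivity profiles under Euclidean
    and affine-invariant Riemannian metrics, together with a synthetic
    dyad-cohort generator with planted cross-dyad edge coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
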