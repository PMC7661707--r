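Package: glioresponse
Title: Therapy-Response Classification of Glioblastoma from MRI Radiomics and MRSI Source Weights
Version: 0.1.0
Authors@R: person("glioresponse", "authors", email = "dev@example.org", role = c("aut", "cre"))
Description: Discriminates treated from control glioblastoma-bearing subjects
    using two magnetic-resonance modalities. From T2-weighted images with
    tumor masks it extracts a 90-feature radiomic description (GLCM, GLRLM,
    GLSZM and NGTDM texture statistics plus Minkowski functionals at 16
    threshold levels). From MRSI voxel spectra it extracts per-voxel mixing
    weights by convex non-negative matrix factorization. Linear classifiers
    (logistic regression, LDA, linear SVM) with filter, embedded and wrapper
    recursive feature elimination are evaluated under grouped
    cross-validation, fused to one decision per subject by slice voting (SVS)
    or voxel voting (VVS), and visualized as anatomically registered
    nosological certainty maps. A seeded synthetic-cohort generator provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
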