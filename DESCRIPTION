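Package: triplanr
Title: Tri-Planar 2.5D Ensemble Segmentation of Sinus CBCT Volumes
Version: 0.1.0
Authors@R:
    person("Imaging", "Tools", email = "imaging.tools@example.org", role = c("aut", "cre"))
Description: End-to-end 2.5D multi-planar ensemble segmentation for volumetric
    imaging of the maxillary sinus. Volumes are decomposed into axial, sagittal
    and coronal slice stacks, segmented per plane with compact U-net family
    networks trained under a multi-label soft Dice loss, fused voxel-wise by
    unanimous, affirmative or majority voting, and the intra-sinus lesion mask
    is derived by subtracting the air region from the whole-sinus prediction.
    Includes a synthetic CBCT-like sinus phantom generator with exact ground
    truth, minimal NIfTI-1 and NRRD readers and writers, volumetric evaluation
    (Jaccard, Dice, precision, recall, per-slice profiles, boxplot statistics,
    ANOVA and paired t comparisons) and a seeded experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
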