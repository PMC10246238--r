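Package: lesionload
Title: Lesion-Load Quantification and Lesion-Symptom Mapping for
    Cerebellar Mutism Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how focal brain lesions disrupt a region of
    interest, with tools developed around the study of post-operative
    cerebellar mutism syndrome (CMS). Computes slice-wise percent-overlap
    lesion load along an oblique slicing axis (e.g. 17 degree oblique
    coronal slices perpendicular to the superior cerebellar peduncles),
    lesion load against a voxel-weighted statistical map, cohort lesion
    overlap and proportional subtraction maps, Welch t-tests with effect
    sizes and dose-response rate binning, and a simplified sparse
    canonical correlation lesion-symptom mapping stage with
    cross-validated sparseness selection. Includes a synthetic phantom
    and cohort generator so every stage is testable without patient
    data, and a pipeline orchestrating the full analysis from a config.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
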