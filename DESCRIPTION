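Package: petburden
Title: Whole-Body PET Tumour Burden Quantification and Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whole-body tumour burden from PSMA PET SUV volumes:
    reference-region (liver sphere / aortic cylinder) threshold derivation,
    isocontour lesion segmentation by 3D connected components, PSMA-derived
    tumour volume (PSMA-TV) and total lesion PSMA (TL-PSMA) aggregation,
    PERCIST-style and biochemical therapy-response classification, and
    inter-method agreement statistics (Bland-Altman on relative differences,
    repeatability coefficients, rank correlations, paired-test power).
    Includes a synthetic phantom generator with known ground truth so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
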