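Package: glymalps
Title: Glymphatic DTI-ALPS Index, Amyloid PET Centiloid and Biomarker
    Statistics on Simulated Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify glymphatic system function from diffusion
    MRI via the DTI-ALPS (diffusion tensor image analysis along the
    perivascular space) index, to quantify amyloid PET as SUV, SUVR and
    centiloid, and to relate these imaging biomarkers to cognition (MMSE)
    and atrophy (VSRAD Z-score) through group comparisons and Pearson
    regression. Includes simulators for white-matter tensor phantoms with
    a perivascular diffusivity component, Rician-noise multi-shell
    diffusion-weighted images, PET SUVR maps, and CN/AD biomarker cohorts
    with a configurable correlation structure, so the whole analysis
    pipeline can be exercised and validated end to end without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
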