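Package: hcsa
Title: Cardiac Phenotyping of Embryonic Hearts by Hemoglobin Contrast
    Subtraction Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies embryonic ventricular function from time-lapse
    heart videomicroscopy using hemoglobin contrast subtraction
    angiography (HCSA). Hemoglobin absorbs short visible wavelengths far
    more strongly than red light, so subtracting a strongly absorbed
    colour channel from a weakly absorbed one yields an endogenous blood
    contrast image without injected dye. The package reads PNG/TIFF
    image series and ventricle ROI sidecar files, classifies
    hemoglobin-containing pixels inside the segmented ventricle with an
    internally implemented Otsu threshold, selects end-diastolic and
    end-systolic frames, and computes per-embryo ventricular metrics
    (total areas, blood areas, stroke area, ejection fraction,
    myocardial mass index). Cohorts are compared with exact
    Mann-Whitney tests and distribution-free median confidence
    intervals. A synthetic beating-heart phantom generator with
    analytic ground truth makes every pipeline stage testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
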