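Package: sirtdose
Title: Partition-Model Dosimetry and Activity Planning for Y-90 Microsphere
    Radioembolization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for selective internal radiation therapy (SIRT) dosimetry
    with Y-90 resin microspheres: a four-compartment partition model (tumor,
    in-target normal liver, out-target normal liver, lungs) that apportions
    injected activity by imaging counts and computes absorbed doses; activity
    planning under lung and normal-liver tolerance limits, the body-surface-
    area method with lung-shunt-based reduction, and the lung shunt fraction
    from conjugate planar views; seeded digital emission phantoms emulating
    Tc-99m MAA SPECT and Y-90 PET acquisitions with known ground truth; and
    paired-modality and dose-stratified progression-free-survival comparison
    of planning versus post-treatment dosimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
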