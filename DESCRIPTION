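Package: lobarquant
Title: Lobar Ventilation/Perfusion Quantification on Digital Thorax Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital anthropomorphic thorax phantoms with five lung lobes and
    known ground-truth lobar tracer fractions; simulation of reconstructed
    ventilation/perfusion SPECT volumes (Gaussian point-spread function,
    Poisson counting noise) and of planar scintigraphy by attenuated forward
    projection through a CT-derived mu-map; lobar quantification by the
    clinical planar equal-thirds template and by 3D lobe counting; simulated
    interobserver variability; and Welch-ANOVA method-comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
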