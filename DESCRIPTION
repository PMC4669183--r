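Package: mr2plan
Title: MR-Only Radiotherapy Treatment Planning for Small-Animal kV Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end MR-only treatment-planning workflow for kilovoltage
    irradiation of the rat brain. Multi-sequence MR volumes (T1, T2, UTE, ZTE)
    are corrected for intensity inhomogeneity by coherent local intensity
    clustering, segmented into air, soft tissue and bone by multi-channel fuzzy
    c-means, converted to bulk-assigned pseudo-CT density and attenuation maps,
    and used for kV ray-trace dose planning. Dose-volume-histogram metrics of
    the MR-planned dose are compared against CT-based reference plans. A
    synthetic rat-head phantom generator with Rician noise and smooth
    multiplicative bias fields makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
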