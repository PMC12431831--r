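Package: rmarct
Title: Regional Model-Based Metal Artifact Reduction for Spectral CT
    Virtual Monochromatic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-domain reduction of metal artifacts in low-energy virtual
    monochromatic images (VMIs) from dual-energy CT. Decomposes a VMI series
    into water/bone material basis images, selects the optimal (least
    artifact-affected) energy with a total-variation cost, segments artifact
    regions with sorting-and-thresholding masks, fits a regional quadratic
    mapping from optimal-VMI CT numbers to each material basis in
    artifact-free pixels, corrects the artifact regions of the basis images,
    and re-synthesizes artifact-reduced VMIs at any energy. Ships a
    dual-layer spectral-CT simulator (polychromatic forward projection,
    beam hardening, photon starvation, filtered back projection) that
    generates artifact-bearing phantom VMI series with ground truth, so the
    whole pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
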