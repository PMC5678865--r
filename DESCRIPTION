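Package: cxcl12grad
Title: Simulating CXCL12 Gradient Dynamics in the Tumor Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid discrete-cell / continuum simulator of chemokine CXCL12
    gradients in a small vascularized tumor section. CXCL12-secreting cells
    and CXCR7+ scavenging cells occupy voxels of a 3D lattice; free chemokine
    diffuses (alternating direction explicit scheme, no-flux boundaries),
    degrades extracellularly, binds reversibly and isoform-specifically to
    extracellular matrix, and is taken up by CXCR7 through a receptor
    trafficking ODE subsystem. A central blood vessel exchanges CXCL12 with
    tissue through a mass-transfer boundary condition, and both cellular
    secretion and blood levels can be forced on a circadian cosine. The
    package provides the two canonical experiment drivers (paired
    source/sink cell clusters; a vascularized section under circadian
    forcing), gradient magnitude/direction metrics, steady-state detection,
    and replicate-averaged cell-composition sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    generics,
    ggplot2,
    withr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
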