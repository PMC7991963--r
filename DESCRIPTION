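Package: ldhdwave
Title: Zernike and Low-Degree/High-Degree Corneal Wavefront Simulation for
    Aspheric Laser Ablations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the anterior corneal surface as a conic section and
    simulates the wavefront changes produced by conventional spherical and
    customized aspheric photorefractive ablations. Surface profiles are
    projected onto the rotationally symmetric Zernike modes up to radial
    order six by scalar products over an optical zone, and the coefficients
    are converted exactly to the low-degree/high-degree (LD/HD) basis whose
    high-degree modes contain no constant or quadratic monomials. Provides
    the paraxial post-operative apical radius computation, a solver for the
    target asphericity that achieves a prescribed change in fourth-order
    Zernike spherical aberration, dioptric spherical-equivalent metrics,
    and scenario engines for spherical-correction, optical-zone and
    asphericity sweeps with CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
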