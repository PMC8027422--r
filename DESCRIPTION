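Package: holotwin
Title: Digital Twin of a Holographic Micromanipulation Microscope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free digital twin of an immersive holographic
    micromanipulation instrument. Renders synthetic three-axis RGB in-line
    holograms of microspheres and bacteria, reconstructs them into volumetric
    images by tilt-compensated Rayleigh-Sommerfeld (angular-spectrum)
    back-propagation and channel overlap, segments the volumes into per-object
    position, size and orientation features, extracts isosurface meshes,
    optimizes holographic optical tweezer phase masks with a weighted
    Gerchberg-Saxton algorithm, fits the trap-space/imaging-space calibration
    transform, and closes the loop with an overdamped Brownian/swimmer dynamics
    simulator of the sample.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    png,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
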