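Package: woodyroot
Title: Field-to-Parameter Pipeline for Root System Architecture of Woody Perennials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and simulating the root system architecture
    (RSA) of woody perennials such as grapevine rootstocks. Parses in-situ
    3D-digitizer point files into topological root systems, reads and writes
    the Root System Markup Language (RSML), extracts architectural traits
    (lengths, convex hulls, depth profiles) and growth-model parameters,
    simulates genotype-specific root growth from a static initial root
    system with a probabilistic gravitropism/plagiotropism objective, and
    computes root hydraulic properties: theoretical axial conductivity of
    elliptical xylem conduits (Hagen-Poiseuille), the standard uptake
    fraction (SUF) of each root segment and whole-root-system conductance
    (Krs) from a Doussan-type water-flow model. Includes synthetic-data
    generators and digitization-accuracy metrics (RMSE, bias, double-point
    deviations) so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    yaml,
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
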