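Package: spindrop
Title: Centrifugal Microfluidic Droplet Emulsification and Separation Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates droplet formation and centrifugal separation in
    lab-on-a-disc microfluidic devices. Provides a planar two-phase
    volume-of-fluid solver in the co-rotating frame (PLIC interface
    reconstruction, continuum-surface-force interfacial tension with wall
    contact angles, PISO-style pressure-velocity coupling, centrifugal,
    Coriolis and Euler body forces), the dimensionless design rules for
    such devices (capillary, Weber, Bond and Rossby numbers, centrifugal
    pumping velocity, dripping/jetting and outlet classification), and
    droplet-population metrics (areas, sphere-equivalent diameters,
    generation rate, coefficient of variation, size histograms).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
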