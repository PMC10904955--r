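Package: chipcyte
Title: Cell Classification and Measurement in Microfluidic-Chip Fluorescence Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable reimplementation of two multi-channel fluorescence
    image-analysis protocols for co-cultured cell populations in
    microfluidic-chip fields of view. Segments nuclei with seed-guided growth,
    classifies cells as marker-positive or marker-negative (GFP vs
    phalloidin-only, or GFP vs RFP), splits touching-cell clumps at equal
    distances between nuclei, enforces nucleation through an 80% overlap
    linking rule, and reports per-object and per-field measurements (counts,
    areas, positions, shape). Includes a seeded synthetic field generator with
    ground-truth masks so every stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
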