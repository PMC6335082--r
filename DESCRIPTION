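Package: arborient
Title: Planar Orientation Analysis of Basal Dendritic Arbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the planar orientation of pyramidal-cell basal
    dendritic arbors relative to four anatomical reference directions
    (posterior, dorsal, anterior, ventral) on horizontal brain sections.
    Reads SWC reconstructions and per-section map documents, resamples
    arbors into 0.5 micrometre segment points, partitions the circle
    around each soma into four anatomical sectors, and calls per-neuron
    orientation two ways: the Fisher circular median direction (with a
    map-level group-tendency rule engine) and the dendritic length ratio
    method (DLRM), which compares the dendritic length fraction per
    sector against the sector's arc fraction at configurable thresholds.
    Includes oriented and expansion circular histogram plots (OCH, ECH),
    a seeded synthetic-morphology generator with von Mises orientation
    bias for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
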