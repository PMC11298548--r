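Package: gliaxon
Title: Calcium Synchrony and Microglia-Axon Interaction Analysis for
    Two-Photon Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo two-photon imaging studies of
    motor-cortex layer-5 calcium dynamics and spinal-cord microglia-axon
    interaction. Implements delta-F-over-F transient detection against a
    percentile baseline, pairwise cosine (non-centered) and Pearson
    synchrony with session standardization, microglial soma extraction by
    half-maximum region growing with equivalent-ellipse morphometry
    (area, aspect ratio, circularity, roundness) and field density,
    Otsu-threshold colocalization of microglia with axons, process-tip
    moving-vector polarity with axial angle folding, and the
    Mardia-Watson-Wheeler uniform-scores test for circular samples.
    Includes seeded synthetic-data generators (correlated calcium traces,
    two-channel image stacks, tip trajectories, von Mises angle samples)
    with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
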