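Package: assemblyscope
Title: Quantification of Neuron and Astrocyte Arrangement in Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated image-analysis pipeline for quantifying the spatial
    arrangement of neurons and astrocytes in coculture micrographs. Implements
    a Fourier-based normalized clustering factor (NCF) computed from the
    radially sampled 2D power spectral density of each fluorescence channel,
    difference-of-disks band-pass detection of DAPI-stained nuclei with
    channel-dominance classification into neurons and glia, per-class cell
    area and density summaries, and a soma-connectivity metric (ratio of total
    to isolated somas) for phase-contrast time courses. Includes a synthetic
    scene generator (Poisson and Thomas point processes, calibration fields)
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
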