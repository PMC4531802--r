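Package: bafish
Title: Detection of Rare Chromosome Breaks and Translocations from
    Break-Apart FISH Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-throughput image analysis for three-color break-apart
    fluorescence in situ hybridization (FISH) of interphase nuclei.
    Segments nuclei from DAPI maximum projections, detects FISH spots per
    channel within nuclear regions of interest, computes per-allele minimum
    inter-signal distances, and calls chromosome breakage and translocation
    events by distance thresholding. Population-level statistics include
    event-positive proportions with modified Wald (Agresti-Coull)
    confidence intervals, pairwise Fisher exact comparisons between
    conditions, and empirical calibration of the proximity threshold from
    negative-control distance distributions. A synthetic-imaging module
    generates multi-channel confocal-like z-stacks of nuclei with
    configurable allele states and exact ground truth, so that every stage
    of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tools,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
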