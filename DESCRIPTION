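Package: osteomorph
Title: Fluorescence Morphometry of Cortical Bone and the Osteocyte
    Lacuno-Canalicular System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry of cortical bone from calibrated
    fluorescence section images and confocal stacks: rule-based and
    trainable-classifier segmentation of pores, Haversian canals and
    osteocytic lacunae; 2D shape descriptors (area, axis lengths,
    perimeter, circularity, smoothness); cortical layer partitioning
    (inner, outer and Haversian lamellae); calcein label classification
    of endosteal, periosteal and intracortical void surfaces; 3D
    separation of lacunae from canaliculi by local thickness with
    skeleton-based length and diameter estimation; and many-to-one
    Dunnett comparisons of treatment groups against a control. Includes
    a seeded synthetic phantom generator with exact ground truth so
    every stage of the pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    igraph,
    mvtnorm,
    ranger,
    stats,
    grDevices,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
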