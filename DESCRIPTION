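Package: spheroclear
Title: Quantitative Evaluation of Optical Clearing in 3D Cell Culture
    Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how optical clearing and embedding protocols
    affect confocal imaging of spheroids and other 3D cell cultures.
    Implements morphometry of clearing-induced shrinkage or swelling from
    maximum projections, depth-resolved intensity and signal-to-noise
    profiles with 50%/90% signal-decay depths and the Rose-criterion cutoff
    depth, and 3D nuclei segmentation by Laplacian-of-Gaussian seeded
    watershed with counting of marker-positive nuclei.  A synthetic
    spheroid-stack simulator with exponential depth attenuation, shrinkage,
    rim-restricted marker expression, z-compensation, and ground-truth
    labels supports validation of every stage, and group-comparison
    statistics (Kruskal-Wallis with Dunn's test, one-way ANOVA with Tukey's
    test) summarise protocol panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    nortest,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
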