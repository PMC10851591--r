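Package: dabquant
Title: Dual-Threshold DAB Immunostaining Quantification and Phenotype
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies DAB immunostaining in brightfield
    photomicrographs of hematoxylin-counterstained tissue. Converts RGB
    images to optical density, unmixes hematoxylin and DAB by linear
    stain separation, builds an inverted 8-bit DAB intensity map with a
    tissue mask, applies a low/high threshold pair to measure total and
    high-density (operationally intracellular) staining through 12
    per-image parameters, aggregates images per patient, clusters
    patients into expression phenotypes by two-dimensional hierarchical
    clustering with Java TreeView export, and compares phenotype groups
    across postnatal-age strata with classical tests. Includes a
    seed-reproducible synthetic histology generator that emits
    hematoxylin+DAB lung-like images with exact ground-truth masks so
    every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    pheatmap,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
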