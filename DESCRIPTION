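Package: telohic
Title: Telomere Hypercluster Analysis from 3C Contact Maps and 3D Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study telomere clustering in budding yeast nuclei from
    chromosome conformation capture (3C/Hi-C) data and 3D fluorescence
    microscopy. Implements restriction-fragment binning of contact data,
    sequential component normalization (matrix balancing), 3D genome
    reconstruction by shortest-path distance completion followed by classical
    multidimensional scaling, telomere and centromere contact statistics,
    and quantification of telomere protein foci in 3D image stacks,
    including hypercluster classification and a concentric nuclear zoning
    assay. A synthetic-data module generates bead-chain nuclear structures,
    contact maps, read pairs and nucleus images with planted ground truth
    for validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Matrix,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
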