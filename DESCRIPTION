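Package: mxmesh
Title: Mesh-Scan Diffraction Scoring, Partial-Dataset Clustering and Merging
    for Multi-Crystal Macromolecular Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-crystal serial synchrotron crystallography
    workflows at desk scale: per-frame diffraction scoring of mesh-scan
    images (iterative background estimation, sharp-ring rejection, Bragg
    spot detection, Wilson-model fitting and a powder-correlation-gated
    diffraction score), heat-map assembly and ranking of collection
    positions, a deterministic simulator of diffraction frames and partial
    reflection wedges, hierarchical cluster analysis of pairwise dataset
    correlations for isomorphous-subset selection, reference-based
    resolution of merohedral indexing ambiguities, and relative scaling and
    inverse-variance merging with standard quality statistics (completeness,
    multiplicity, R_merge, R_pim, CC_1/2, Yeates H-test twin fraction) plus
    a Crick-Magdoff-style theoretical anomalous diffraction ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    igraph,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
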