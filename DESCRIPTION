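Package: GradientParcellation
Title: Connectome Parcellation by Reversals in Diffusion-Embedding Gradients
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Splits a voxelized connectome into a hierarchy of spatially
    contiguous regions by detecting reversals in the spatial gradients of
    diffusion-embedding components, the connectivity analogue of drawing
    borders at retinotopic gradient reversals. Provides diffusion embedding
    of directed connection-strength matrices, per-pixel gradient fields in a
    flattened view, two border-placement strategies (explicit reversal
    detection via border maps and Dijkstra distances, and density clustering
    of weighted gradient cosine distances), post-processing into contiguous
    labeled regions, a recursive driver that builds a region hierarchy,
    synthetic toy-model connectome generators with ground-truth
    parcellations, and evaluation statistics (uncertainty coefficient,
    modularity, intersection-over-union, random control parcellations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    cluster,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
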