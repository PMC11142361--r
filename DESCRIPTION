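Package: cocost
Title: Contrastive Graph Feature Representation for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns low-dimensional contrastive feature representations for
    spatially resolved transcriptomics by comparing a target tissue slice
    against a background slice. A k-nearest-neighbor heat-kernel affinity
    graph is built for each slice, converted into a graph Laplacian
    smoothing filter, and a projection is obtained from the eigenvectors of
    the difference of the two graph-filtered gene scatter matrices. This
    emphasizes spatial expression programs enriched in the target slice
    while suppressing dominant high-variance structure shared with the
    background. Includes a kernelized (RKHS) variant, a synthetic
    paired-slice generator with planted spatial domains, embedding
    clustering helpers, readers for 10x-style MTX and delimited matrices,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    mclust,
    igraph,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
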