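Package: ManifoldReg
Title: Multi-Modal Image Registration via Laplacian Eigenmap Structural
    Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms pairs of multi-modal 2-D grayscale images (e.g. CT
    versus MR, or differently weighted MR sequences) into a shared
    mono-modal intensity coordinate system, so that standard mono-modal
    registration machinery applies.  Every pixel-centered patch of an image
    is treated as a point in patch space; a symmetric k-nearest-neighbour
    graph with heat-kernel weights is built on this point cloud and the
    smallest non-trivial generalized eigenvectors of its graph Laplacian
    yield modality-insensitive "feature images".  The two embeddings are
    aligned by principal-component rigid-body alignment after correcting
    the per-eigenvector sign (reflection) ambiguity.  Registration backends
    include mean-squared-error rigid registration with a regular-step
    gradient-descent optimizer for fully overlapping images and
    Fourier-Mellin log-polar phase correlation for partially overlapping
    images, plus histogram mutual information and landmark error metrics
    and a synthetic brain-phantom generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RANN,
    RSpectra,
    igraph,
    EBImage,
    png,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'image-io.R'
    'patch-manifold.R'
    'laplacian-eigenmap.R'
    'manifold-alignment.R'
    'transforms.R'
    'registration-rigid.R'
    'registration-fmt.R'
    'registration-pipeline.R'
    'metrics.R'
    'synthetic-data.R'
    'show-methods.R'
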