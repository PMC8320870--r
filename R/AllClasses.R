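#' @import methods
#' @importFrom Matrix Diagonal sparseMatrix forceSymmetric rowSums t solve
#'   Cholesky diag
#' @importFrom RANN nn2
#' @importFrom RSpectra eigs_sym
#' @importFrom igraph graph_from_adjacency_matrix components
#' @importFrom stats fft runif rnorm cov median
#' @importFrom utils write.table read.table
#' @importFrom EBImage resize gblur Image imageData
#' @importFrom png readPNG writePNG
#' @importFrom tiff readTIFF
#' @importFrom RNifti readNifti
NULL

#' Patch point cloud of a grayscale image
#'
#' Every pixel of an \code{nr x nc} image owns one \code{s x s} patch
#' (replicate-edge padded at the border), vectorized into a row of an
#' \code{N x D} matrix with \code{N = nr * nc} and \code{D = s^2}.  Rows are
#' in raster order (row-major over pixel coordinates), so row
#' \code{(r - 1) * nc + c} holds the patch centered at pixel \code{(r, c)};
#' that fixed ordering is the index map between matrix rows and pixels.
#'
#' @slot points numeric matrix, \code{N x D}, patch intensities in [0, 1].
#' @slot imageDim integer vector \code{c(nr, nc)}.
#' @slot patchSide odd integer patch side \code{s}.
#' @export
setClass("PatchCloud",
  representation(points = "matrix", imageDim = "integer",
                 patchSide = "integer"),
  validity = function(object) {
    s <- object@patchSide
    if (length(s) != 1L || s < 1L || s %% 2L == 0L)
      return("patchSide must be a single odd positive integer")
    if (length(object@imageDim) != 2L || any(object@imageDim < 1L))
      return("imageDim must be two positive integers")
    if (nrow(object@points) != prod(object@imageDim))
      return("points must have one row per pixel (N = nr * nc)")
    if (ncol(object@points) != s^2)
      return("points must have patchSide^2 columns")
    TRUE
  })

#' Symmetric k-nearest-neighbour graph on a patch cloud
#'
#' Undirected graph over the \code{N} patch points.  In \code{"symmetric"}
#' mode an edge (i, j) exists iff j is among i's k nearest neighbours
#' \emph{or} i is among j's; in \code{"mutual"} mode both must hold.  Edges
#' are stored once with \code{edges[, 1] < edges[, 2]}, together with their
#' squared Euclidean patch-space distances.
#'
#' @slot nNodes number of nodes \code{N}.
#' @slot edges integer matrix, m x 2, each row an edge with lo < hi.
#' @slot distSq squared Euclidean edge lengths (length m).
#' @slot k neighbour count parameter.
#' @slot mode \code{"symmetric"} or \code{"mutual"}.
#' @export
setClass("NeighborGraph",
  representation(nNodes = "integer", edges = "matrix", distSq = "numeric",
                 k = "integer", mode = "character"),
  validity = function(object) {
    if (!object@mode %in% c("symmetric", "mutual"))
      return("mode must be 'symmetric' or 'mutual'")
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e) != length(object@distSq))
      return("distSq must have one entry per edge")
    if (nrow(e) > 0L) {
      if (any(e < 1L) || any(e > object@nNodes))
        return("edge endpoints out of range")
      if (any(e[, 1L] >= e[, 2L]))
        return("edges must satisfy lo < hi (no self-loops, stored once)")
    }
    TRUE
  })

#' Graph Laplacian system L = D - W
#'
#' Sparse symmetric Laplacian of a weighted neighbour graph, its degree
#' vector, and the number of connected components (determined from graph
#' connectivity, not from eigenvalue counting).
#'
#' @slot L sparse symmetric N x N Laplacian.
#' @slot W sparse symmetric N x N weight matrix (zero diagonal).
#' @slot degree row sums of W.
#' @slot nComponents number of connected components of the graph.
#' @slot sigmaSq heat-kernel bandwidth used for W (0 = simple-minded weights).
#' @export
setClass("LaplacianSystem",
  representation(L = "Matrix", W = "Matrix", degree = "numeric",
                 nComponents = "integer", sigmaSq = "numeric"),
  validity = function(object) {
    n <- nrow(object@L)
    if (ncol(object@L) != n) return("L must be square")
    if (length(object@degree) != n) return("degree length must match L")
    if (object@nComponents < 1L) return("nComponents must be >= 1")
    TRUE
  })

#' Low-dimensional spectral embedding of an image's patch manifold
#'
#' \code{N x d} matrix of coordinates: column j is the generalized
#' eigenvector of \code{L y = lambda D y} paired with the j-th smallest
#' eigenvalue strictly above the zero cluster (one zero eigenvalue per
#' connected component is discarded).  Each column is normalized to
#' \code{y' D y = 1} with a canonical sign (first non-negligible entry
#' positive).  Rows follow the raster pixel order of the originating
#' \linkS4class{PatchCloud}, so columns reshape to feature images.
#'
#' @slot coords numeric matrix, N x d.
#' @slot eigenvalues the d retained eigenvalues, ascending, all > 0.
#' @slot imageDim originating image dimensions \code{c(nr, nc)}.
#' @slot nDiscarded number of zero-cluster eigenvectors dropped.
#' @export
setClass("ManifoldEmbedding",
  representation(coords = "matrix", eigenvalues = "numeric",
                 imageDim = "integer", nDiscarded = "integer"),
  validity = function(object) {
    if (ncol(object@coords) != length(object@eigenvalues))
      return("one eigenvalue per embedding column required")
    if (length(object@imageDim) == 2L &&
        nrow(object@coords) != prod(object@imageDim))
      return("coords rows must equal nr * nc")
    if (is.unsorted(object@eigenvalues))
      return("eigenvalues must be ascending")
    TRUE
  })

#' Principal frame (PCA) of an embedded point cloud
#'
#' @slot centroid d-vector mean of the points.
#' @slot directions orthonormal d x d matrix, columns are principal
#'   directions ordered by descending variance, sign-canonicalized so each
#'   column's largest-magnitude entry is positive.
#' @slot variances eigenvalues of the covariance matrix, descending.
#' @export
setClass("PrincipalFrame",
  representation(centroid = "numeric", directions = "matrix",
                 variances = "numeric"),
  validity = function(object) {
    d <- length(object@centroid)
    if (!all(dim(object@directions) == d))
      return("directions must be d x d")
    if (length(object@variances) != d)
      return("variances must have length d")
    if (is.unsorted(rev(object@variances)))
      return("variances must be descending")
    TRUE
  })

#' Result of aligning a sensed embedding to a reference embedding
#'
#' Records the per-axis sign flips applied to resolve eigenvector
#' reflection ambiguity, the proper rotation \code{R = B A'} between the
#' principal frames, the two centroids, and the aligned sensed coordinates
#' \code{p' = R (p - cs) + cr}.
#'
#' @slot rotation d x d proper rotation (det +1).
#' @slot signFlips vector of +/-1 per embedding axis.
#' @slot centroidSensed,centroidRef d-vectors.
#' @slot covariances per-axis covariance used by the sign test.
#' @slot aligned aligned sensed embedding (a ManifoldEmbedding).
#' @export
setClass("ManifoldAlignment",
  representation(rotation = "matrix", signFlips = "numeric",
                 centroidSensed = "numeric", centroidRef = "numeric",
                 covariances = "numeric", aligned = "ManifoldEmbedding"),
  validity = function(object) {
    if (!all(object@signFlips %in% c(-1, 1)))
      return("signFlips must be +/-1")
    d <- nrow(object@rotation)
    if (ncol(object@rotation) != d) return("rotation must be square")
    if (max(abs(crossprod(object@rotation) - diag(d))) > 1e-6)
      return("rotation must be orthonormal")
    TRUE
  })

#' 2-D similarity transform (rotation, translation, isotropic scale)
#'
#' Maps a point p (0-based (x, y) = (column, row) coordinates) to
#' \code{scale * R(theta) (p - center) + center + (tx, ty)}, with the
#' rotation center at the geometric image center
#' \code{((nc - 1) / 2, (nr - 1) / 2)} by convention.  \code{scale = 1}
#' gives a rigid transform.
#'
#' @slot theta rotation angle in radians.
#' @slot tx,ty translations in pixels.
#' @slot scale isotropic scale factor (> 0).
#' @slot center rotation center, 0-based (x, y).
#' @export
setClass("SimilarityTransform2D",
  representation(theta = "numeric", tx = "numeric", ty = "numeric",
                 scale = "numeric", center = "numeric"),
  validity = function(object) {
    if (object@scale <= 0) return("scale must be positive")
    if (length(object@center) != 2L) return("center must be (x, y)")
    if (!all(is.finite(c(object@theta, object@tx, object@ty, object@scale))))
      return("transform parameters must be finite")
    TRUE
  })

#' Outcome of a registration run
#'
#' @slot transform estimated \linkS4class{SimilarityTransform2D} that maps
#'   the sensed image into alignment with the reference.
#' @slot metric final metric value (MSE for rigid, correlation peak for
#'   Fourier-Mellin).
#' @slot iterations optimizer iterations (0 for Fourier methods).
#' @slot converged logical success flag.
#' @slot trace per-iteration metric values.
#' @slot method \code{"rigid"}, \code{"fmt"} or \code{"pipeline"}.
#' @slot details free-form list (stage outputs, feature images, ...).
#' @export
setClass("RegistrationResult",
  representation(transform = "SimilarityTransform2D", metric = "numeric",
                 iterations = "integer", converged = "logical",
                 trace = "numeric", method = "character", details = "list"),
  validity = function(object) {
    if (length(object@trace) && !all(is.finite(object@trace)))
      return("metric trace must be finite")
    TRUE
  })

#' Synthetic structured phantom
#'
#' Nested perturbed-ellipse "tissues" on a background, with a label map and
#' at least five landmark points inside the object, used to emulate brain
#' slices for ground-truth experiments.
#'
#' @slot image base intensity image in [0, 1] (labels / max label).
#' @slot labels integer label map, 0 = background.
#' @slot landmarks k x 2 matrix of 0-based (x, y) points inside the object.
#' @export
setClass("Phantom",
  representation(image = "matrix", labels = "matrix", landmarks = "matrix"),
  validity = function(object) {
    if (!all(dim(object@image) == dim(object@labels)))
      return("image and labels must agree in shape")
    if (ncol(object@landmarks) != 2L) return("landmarks must be k x 2")
    if (nrow(object@landmarks) < 5L) return("at least 5 landmarks required")
    TRUE
  })

#' Tissue-intensity lookup defining a simulated modality
#'
#' @slot levels intensity per label (levels[l + 1] for label l), in [0, 1].
#' @slot gamma smooth intensity nonlinearity exponent (1 = none).
#' @slot noiseSigma additive Gaussian noise s.d. (fraction of range).
#' @slot biasAmplitude low-frequency multiplicative bias field amplitude.
#' @slot smoothSigma partial-volume Gaussian blur s.d. in pixels.
#' @slot name preset name.
#' @export
setClass("ModalityMap",
  representation(levels = "numeric", gamma = "numeric", noiseSigma = "numeric",
                 biasAmplitude = "numeric", smoothSigma = "numeric",
                 name = "character"),
  validity = function(object) {
    if (any(object@levels < 0 | object@levels > 1))
      return("levels must lie in [0, 1]")
    if (object@gamma <= 0) return("gamma must be positive")
    if (object@noiseSigma < 0 || object@biasAmplitude < 0)
      return("noiseSigma and biasAmplitude must be non-negative")
    TRUE
  })

#' Reference/sensed multi-modal pair with known ground truth
#'
#' The sensed image is the second modality of the same phantom, warped by a
#' known similarity transform, optionally cropped to a partial-overlap
#' window, with seeded noise.  \code{trueTransform} is the aligning
#' transform: applying it to the sensed image reproduces the reference
#' geometry.
#'
#' @slot reference,sensed grayscale images in [0, 1].
#' @slot trueTransform ground-truth aligning SimilarityTransform2D.
#' @slot overlapFraction fraction of the object retained in the sensed
#'   frame, in (0, 1].
#' @slot landmarks reference-frame landmarks (from the phantom).
#' @slot seed generator seed (regeneration is bit-identical).
#' @export
setClass("PhantomPair",
  representation(reference = "matrix", sensed = "matrix",
                 trueTransform = "SimilarityTransform2D",
                 overlapFraction = "numeric", landmarks = "matrix",
                 seed = "integer"),
  validity = function(object) {
    if (object@overlapFraction <= 0 || object@overlapFraction > 1)
      return("overlapFraction must be in (0, 1]")
    TRUE
  })
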