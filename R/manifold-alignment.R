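#' Principal frame (PCA) of an embedded point cloud
#'
#' Eigen-decomposition of the covariance matrix of the centered
#' coordinates.  Directions are ordered by descending variance, with ties
#' broken stably by original axis index, and each direction's
#' largest-magnitude entry is made positive so that PCA's own sign
#' ambiguity is removed before any frame matching.  A rank-deficient
#' covariance yields a warning and zero-variance axes last.
#'
#' @param x a \linkS4class{ManifoldEmbedding} or an n x d coordinate
#'   matrix.
#' @return a \linkS4class{PrincipalFrame}.
#' @export
principalFrame <- function(x) {
  Y <- if (is(x, "ManifoldEmbedding")) coords(x) else as.matrix(x)
  n <- nrow(Y); d <- ncol(Y)
  if (n < d + 1L) stop("need at least d + 1 points for a principal frame")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr)
  V <- crossprod(Yc) / n
  e <- eigen(V, symmetric = TRUE)      # eigenvalues descending
  vals <- pmax(e$values, 0)
  if (any(vals < 1e-12 * max(vals, 1e-300)))
    warning("rank-deficient covariance: zero-variance axes placed last")
  dirs <- e$vectors
  # stable tie-break: within numerically tied eigenvalues, order columns
  # by the index of their largest-magnitude entry
  grp <- cumsum(c(TRUE, diff(vals) < -1e-12 * max(vals, 1e-300)))
  lead <- apply(abs(dirs), 2L, which.max)
  o <- order(grp, lead)
  dirs <- dirs[, o, drop = FALSE]; vals <- vals[o]
  for (j in seq_len(d)) {
    m <- which.max(abs(dirs[, j]))
    if (dirs[m, j] < 0) dirs[, j] <- -dirs[, j]
  }
  new("PrincipalFrame", centroid = ctr, directions = dirs, variances = vals)
}

#' Correct per-axis reflection (sign) ambiguity between two embeddings
#'
#' An eigenvector and its negation are equally valid, so independently
#' computed embeddings of the two images may be reflected along any axis.
#' Axes are paired by eigenvalue rank (feature image j with feature image
#' j) and, for each pair, the covariance between the reference and sensed
#' coordinates over raster-aligned pixel indices is computed; a negative
#' association means the sensed axis is reflected and it is multiplied by
#' -1.  This presumes the two images roughly share framing; severe initial
#' misalignment weakens the covariance signal.
#'
#' @param reference,sensed \linkS4class{ManifoldEmbedding}s (or matrices)
#'   with equal dimensions over the same working pixel grid.
#' @return list with elements \code{coords} (sign-corrected sensed
#'   coordinates), \code{signFlips} (vector of +/-1) and
#'   \code{covariances}.
#' @export
signCorrect <- function(reference, sensed) {
  R <- if (is(reference, "ManifoldEmbedding")) coords(reference)
       else as.matrix(reference)
  S <- if (is(sensed, "ManifoldEmbedding")) coords(sensed)
       else as.matrix(sensed)
  if (!all(dim(R) == dim(S)))
    stop("embeddings must agree in point count and dimension")
  covs <- vapply(seq_len(ncol(R)),
                 function(j) stats::cov(R[, j], S[, j]), numeric(1L))
  flips <- ifelse(covs < 0, -1, 1)
  list(coords = sweep(S, 2L, flips, `*`), signFlips = flips,
       covariances = covs)
}

.stabilizedDirections <- function(frame, tieTol = 0.05) {
  # within groups of numerically tied variances the covariance
  # eigenvectors are arbitrary rotations of the degenerate subspace, and
  # two independently computed frames would disagree by a random rotation
  # there; replace each tied block by the axis-aligned orthonormal basis
  # of its span so both frames degrade toward the identity together,
  # while well-separated variances keep their exact principal directions
  v <- frame@variances
  d <- length(v)
  top <- max(v, 1e-300)
  grp <- cumsum(c(TRUE, diff(v) < -tieTol * top))
  dirs <- frame@directions
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    Vg <- dirs[, idx, drop = FALSE]
    P <- Vg %*% t(Vg)
    axes <- order(diag(P), decreasing = TRUE)[seq_along(idx)]
    Q <- qr.Q(qr(P[, sort(axes), drop = FALSE]))
    for (j in seq_len(ncol(Q))) {
      m <- which.max(abs(Q[, j]))
      if (Q[m, j] < 0) Q[, j] <- -Q[, j]
    }
    dirs[, idx] <- Q
  }
  dirs
}

#' Rigid-body alignment of two embeddings via their principal frames
#'
#' After sign correction, the rotation \code{R = B A'} maps the principal
#' directions A of the sensed cloud onto the directions B of the reference
#' cloud, and points are aligned as \code{p' = R (p - cs) + cr} where cs
#' and cr are the two centroids.  If the frame match has determinant -1
#' (an odd number of anti-parallel axes) the lowest-variance sensed
#' direction is flipped so R stays a proper rotation.  Variances tied
#' within \code{tieTol} (relative) span degenerate subspaces where
#' principal directions carry no information; there both frames are
#' replaced by stabilized axis-aligned bases (see Details), so the
#' rotation reduces to the identity on fully degenerate clouds instead of
#' amplifying noise into an arbitrary rotation.
#'
#' @param reference,sensed \linkS4class{ManifoldEmbedding}s over the same
#'   working grid.
#' @param tieTol relative variance gap below which axes count as tied.
#' @return a \linkS4class{ManifoldAlignment}.
#' @export
alignEmbeddings <- function(reference, sensed, tieTol = 0.05) {
  refEmb <- if (is(reference, "ManifoldEmbedding")) reference
            else new("ManifoldEmbedding", coords = as.matrix(reference),
                     eigenvalues = seq_len(ncol(as.matrix(reference))) * 0,
                     imageDim = c(nrow(as.matrix(reference)), 1L),
                     nDiscarded = 0L)
  senEmb <- if (is(sensed, "ManifoldEmbedding")) sensed
            else new("ManifoldEmbedding", coords = as.matrix(sensed),
                     eigenvalues = seq_len(ncol(as.matrix(sensed))) * 0,
                     imageDim = c(nrow(as.matrix(sensed)), 1L),
                     nDiscarded = 0L)
  sc <- signCorrect(coords(refEmb), coords(senEmb))
  fr <- principalFrame(coords(refEmb))
  fs <- principalFrame(sc$coords)
  if (any(fs@variances < 1e-12 * max(fs@variances, 1e-300)) ||
      any(abs(diff(fs@variances)) < 1e-12 * max(fs@variances, 1e-300)))
    warning("degenerate principal frame (tied or zero variances); ",
            "alignment proceeds with stable tie-breaking")
  A <- .stabilizedDirections(fs, tieTol)
  B <- .stabilizedDirections(fr, tieTol)
  R <- B %*% t(A)
  if (det(R) < 0) {                       # improper match: flip weakest axis
    A[, ncol(A)] <- -A[, ncol(A)]
    R <- B %*% t(A)
  }
  aligned <- sweep(sc$coords, 2L, fs@centroid) %*% t(R)
  aligned <- sweep(aligned, 2L, fr@centroid, `+`)
  alignedEmb <- senEmb
  alignedEmb@coords <- aligned
  alignedEmb@imageDim <- refEmb@imageDim
  new("ManifoldAlignment", rotation = R, signFlips = sc$signFlips,
      centroidSensed = fs@centroid, centroidRef = fr@centroid,
      covariances = sc$covariances, aligned = alignedEmb)
}

#' Feature images of an aligned embedding
#'
#' Reshapes the aligned sensed coordinates into image geometry and min-max
#' rescales each to [0, 1]; together with the reference's own feature
#' images these use comparable relative intensity levels, completing the
#' multi-modal to mono-modal transformation.
#'
#' @param alignment a \linkS4class{ManifoldAlignment}.
#' @param dim image dimensions \code{c(nr, nc)}.
#' @return list of d matrices in [0, 1].
#' @export
alignedFeatureImages <- function(alignment, dim = alignment@aligned@imageDim)
  featureImages(alignment@aligned, dim)

#' Serialize an alignment report to JSON
#'
#' @param alignment a \linkS4class{ManifoldAlignment}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAlignmentReport <- function(alignment, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write alignment reports")
  rep <- list(signFlips = alignment@signFlips,
              covariances = alignment@covariances,
              rotation = alignment@rotation,
              centroidSensed = alignment@centroidSensed,
              centroidRef = alignment@centroidRef)
  jsonlite::write_json(rep, path, digits = NA, pretty = TRUE)
  invisible(path)
}
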