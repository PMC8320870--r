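#' Build a k-nearest-neighbour graph on a patch cloud
#'
#' Exact Euclidean k-nearest neighbours (kd-tree) define a directed graph
#' which is made undirected either by keeping every one-way edge
#' (\code{"symmetric"} kNN graph: edge iff either endpoint lists the other)
#' or by keeping only reciprocated ones (\code{"mutual"}).  The symmetric
#' rule is the default; it tends toward a single connected component and a
#' forgiving choice of k.
#'
#' @param cloud a \linkS4class{PatchCloud}, or a plain numeric matrix of
#'   points (rows = observations).
#' @param k neighbour count, \code{1 <= k < N}.
#' @param mode \code{"symmetric"} or \code{"mutual"}.
#' @return a \linkS4class{NeighborGraph}.
#' @export
buildKnnGraph <- function(cloud, k = 10L, mode = c("symmetric", "mutual")) {
  mode <- match.arg(mode)
  pts <- if (is(cloud, "PatchCloud")) cloud@points else as.matrix(cloud)
  N <- nrow(pts)
  if (N == 0L) stop("empty point cloud")
  k <- as.integer(k)
  if (k < 1L || k >= N) stop("k must satisfy 1 <= k < N")
  nn <- RANN::nn2(pts, k = k + 1L)
  idx <- nn$nn.idx; dst <- nn$nn.dists
  # the query point itself is normally its own 0-distance neighbour but
  # duplicated points can displace it; drop one self-match per row
  from <- rep(seq_len(N), k + 1L)
  to <- as.vector(idx); d <- as.vector(dst)
  selfpos <- which(to == from)
  selfrow <- from[selfpos]
  drop <- selfpos[!duplicated(selfrow)]
  missing <- setdiff(seq_len(N), selfrow)
  if (length(missing))  # self not found (tied duplicates): drop last column
    drop <- c(drop, (k * N) + missing)
  from <- from[-drop]; to <- to[-drop]; d <- d[-drop]
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- (lo - 1) * N + hi
  if (mode == "mutual") {
    keep <- key %in% key[duplicated(key)]
    lo <- lo[keep]; hi <- hi[keep]; d <- d[keep]; key <- key[keep]
  }
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]; d <- d[!dup]
  ok <- lo != hi
  o <- order(lo[ok], hi[ok])
  new("NeighborGraph", nNodes = N,
      edges = cbind(lo = lo[ok][o], hi = hi[ok][o]), distSq = (d[ok][o])^2,
      k = k, mode = mode)
}

#' Heat-kernel bandwidth from the maximum squared edge length
#'
#' Sets the squared bandwidth sigma^2 to the maximum squared Euclidean
#' distance over graph edges.  With heat-kernel weights
#' \code{exp(-dist^2 / (2 sigma^2))} this bounds every edge weight between
#' \code{exp(-1/2)} (about 0.606, attained on the longest edge) and 1.  A
#' bandwidth of exactly 0 (all connected points coincide) signals the
#' simple-minded weighting fallback (all edge weights 1).
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @return squared bandwidth (scalar >= 0).
#' @export
computeBandwidth <- function(graph) {
  if (nrow(graph@edges) == 0L) stop("graph has no edges")
  max(graph@distSq)
}

#' Heat-kernel edge weights
#'
#' Weight \code{w_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))} on graph edges,
#' zero elsewhere.  If \code{sigmaSq} is 0 the simple-minded scheme is used
#' (unit weight on every edge), the limiting case of an infinite bandwidth.
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @param sigmaSq squared bandwidth, typically from
#'   \code{\link{computeBandwidth}}.
#' @return sparse symmetric N x N weight matrix with zero diagonal.
#' @export
computeWeights <- function(graph, sigmaSq = computeBandwidth(graph)) {
  if (sigmaSq < 0) stop("sigmaSq must be non-negative")
  w <- if (sigmaSq == 0) rep(1, length(graph@distSq))
       else exp(-graph@distSq / (2 * sigmaSq))
  lo <- graph@edges[, 1L]; hi <- graph@edges[, 2L]
  Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                       dims = c(graph@nNodes, graph@nNodes))
}

#' Assemble the graph Laplacian L = D - W
#'
#' Builds the diagonal degree matrix \code{d_ii = sum_j w_ij} and the
#' sparse symmetric Laplacian.  The number of connected components is read
#' from graph connectivity (not from eigenvalue thresholding); it equals
#' the multiplicity of the zero eigenvalue.  A disconnected graph is
#' accepted with a warning (a larger k or pre-smoothing is advisable).
#'
#' @param W sparse symmetric weight matrix (from
#'   \code{\link{computeWeights}}).
#' @param sigmaSq bandwidth used to build W, carried for provenance.
#' @return a \linkS4class{LaplacianSystem}.
#' @export
buildLaplacian <- function(W, sigmaSq = NA_real_) {
  W <- methods::as(W, "CsparseMatrix")
  if (max(abs(W - Matrix::t(W))) > 1e-12 * max(abs(W@x), 1))
    stop("weight matrix must be symmetric")
  if (any(Matrix::diag(W) != 0))
    stop("weight matrix must have zero diagonal")
  deg <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(x = deg) - W
  g <- igraph::graph_from_adjacency_matrix(W != 0, mode = "undirected")
  ncomp <- igraph::components(g)$no
  if (ncomp > 1L)
    warning("graph has ", ncomp, " connected components; consider a ",
            "larger k or smoothing the input")
  new("LaplacianSystem", L = Matrix::forceSymmetric(L), W = W, degree = deg,
      nComponents = as.integer(ncomp), sigmaSq = sigmaSq)
}

#' Spectral embedding from the generalized eigenproblem L y = lambda D y
#'
#' Solves for the \code{nComponents + d} smallest generalized eigenpairs
#' and discards the zero cluster (exactly one eigenvector per connected
#' component), returning the next d eigenvectors with eigenvalues
#' ascending.  Internally the symmetric pencil is reduced to the
#' normalized adjacency \code{D^-1/2 W D^-1/2}, whose largest eigenvalues
#' correspond one-to-one with the smallest generalized eigenvalues; these
#' extremal pairs are computed by implicitly restarted Lanczos iteration
#' with a seeded deterministic start vector.  If Lanczos fails to converge
#' the solver falls back to shift-invert on a sparse Cholesky
#' factorization.  Columns are scaled to \code{y' D y = 1} with the first
#' non-negligible entry made positive (eigenvector sign is arbitrary; a
#' canonical choice keeps runs reproducible, while cross-image sign
#' mismatch is the alignment step's job).
#'
#' @param system a \linkS4class{LaplacianSystem}.
#' @param d embedding dimension (columns returned).
#' @param seed integer seed for the Lanczos start vector.
#' @param tol solver tolerance.
#' @param maxiter solver iteration cap.
#' @return a \linkS4class{ManifoldEmbedding} (slot \code{imageDim} is
#'   filled by \code{\link{imageEmbedding}}; here it is left as the point
#'   count in one row).
#' @export
embedManifold <- function(system, d = 3L, seed = 1L, tol = 1e-9,
                          maxiter = 5000L) {
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  N <- nrow(system@L)
  ncomp <- system@nComponents
  if (d + ncomp > N) stop("d too large: d + nComponents must be <= N")
  if (any(system@degree <= 0))
    stop("isolated node (zero degree); the graph must cover all points")
  k <- ncomp + d
  dm12 <- 1 / sqrt(system@degree)
  A <- Matrix::Diagonal(x = dm12) %*% system@W %*% Matrix::Diagonal(x = dm12)
  A <- methods::as(methods::as(Matrix::forceSymmetric(A), "generalMatrix"),
                   "CsparseMatrix")
  ncv <- min(N, max(40L, 4L * k))
  if (N <= max(64L, 2L * k + 2L)) {
    # tiny systems: a dense solve is exact and avoids Lanczos breakdown
    e <- eigen(as.matrix(A), symmetric = TRUE)
    res <- list(values = e$values[seq_len(k)],
                vectors = e$vectors[, seq_len(k), drop = FALSE], nconv = k)
  } else {
  v0 <- withSeed(seed, stats::runif(N, -1, 1))
  res <- tryCatch(
    RSpectra::eigs_sym(A, k = k, which = "LA",
                       opts = list(ncv = ncv, tol = tol,
                                   maxitr = maxiter, initvec = v0)),
    error = function(e) NULL)
  if (is.null(res) || res$nconv < k) {
    # shift-invert fallback on the normalized Laplacian I - A
    C <- Matrix::Diagonal(N) - A
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(C) +
                             1e-3 * Matrix::Diagonal(N),
                           LDL = FALSE, super = TRUE)
    op <- function(x, args) as.numeric(Matrix::solve(args, x, system = "A"))
    res <- RSpectra::eigs_sym(op, k = k, which = "LA", n = N, args = ch,
                              opts = list(ncv = ncv, tol = tol,
                                          maxitr = maxiter, initvec = v0))
    if (res$nconv < k)
      stop("eigensolver did not converge: ", res$nconv, " of ", k,
           " pairs after ", maxiter, " iterations (tol ", tol, ")")
    res$values <- 1 - (1 / res$values - 1e-3)   # back to adjacency scale
  }
  }
  lambda <- 1 - res$values                       # generalized eigenvalues
  o <- order(lambda)
  lambda <- lambda[o]
  Z <- res$vectors[, o, drop = FALSE]
  keep <- (ncomp + 1L):k
  Y <- Z[, keep, drop = FALSE] * dm12            # y = D^-1/2 z, y'Dy = z'z
  for (j in seq_len(ncol(Y))) {
    yj <- Y[, j]
    nz <- which(abs(yj) > 1e-12 * max(abs(yj)))[1L]
    sgn <- sign(yj[nz])
    Y[, j] <- yj / sqrt(sum(yj^2 * system@degree)) * sgn
  }
  new("ManifoldEmbedding", coords = Y, eigenvalues = lambda[keep],
      imageDim = c(N, 1L), nDiscarded = ncomp)
}

#' One-call spectral embedding of an image
#'
#' Convenience pipeline: patch extraction, kNN graph, max-edge heat-kernel
#' bandwidth, Laplacian, and generalized eigensolve; the returned embedding
#' carries the image geometry so its columns reshape to feature images.
#'
#' @param image numeric matrix in [0, 1].
#' @param patchSide odd patch side (default 3, i.e. D = 9).
#' @param k neighbour count (default 10; 20 is a conservative preset for
#'   noisy inputs).
#' @param d embedding dimension (default 3).
#' @param knnMode "symmetric" or "mutual".
#' @param sigmaSq heat-kernel bandwidth override; NULL (default) applies
#'   the max-squared-edge rule.
#' @param seed,tol,maxiter eigensolver controls, see
#'   \code{\link{embedManifold}}.
#' @return a \linkS4class{ManifoldEmbedding} with \code{imageDim} set.
#' @export
imageEmbedding <- function(image, patchSide = 3L, k = 10L, d = 3L,
                           knnMode = "symmetric", sigmaSq = NULL,
                           seed = 1L, tol = 1e-9, maxiter = 5000L) {
  if (diff(range(image)) == 0)
    stop("degenerate input: constant image has no eigen-structure")
  cloud <- extractPatches(image, patchSide)
  graph <- buildKnnGraph(cloud, k = k, mode = knnMode)
  s2 <- if (is.null(sigmaSq)) computeBandwidth(graph) else sigmaSq
  W <- computeWeights(graph, s2)
  sys <- buildLaplacian(W, sigmaSq = s2)
  emb <- embedManifold(sys, d = d, seed = seed, tol = tol, maxiter = maxiter)
  emb@imageDim <- cloud@imageDim
  emb
}

#' Write / read an embedding as a plain columnar text file
#'
#' Tab-separated coordinates, one row per point, preceded by comment
#' header lines carrying the eigenvalues, image dimensions and the
#' zero-cluster count, so a round trip restores the full object.
#'
#' @param embedding a \linkS4class{ManifoldEmbedding}.
#' @param path output (input) file path.
#' @return \code{writeEmbedding}: invisibly, the path;
#'   \code{readEmbedding}: a \linkS4class{ManifoldEmbedding}.
#' @export
writeEmbedding <- function(embedding, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# eigenvalues:",
          paste(format(embedding@eigenvalues, digits = 17), collapse = "\t")),
    paste("# imageDim:", paste(embedding@imageDim, collapse = "\t")),
    paste("# nDiscarded:", embedding@nDiscarded)), con)
  utils::write.table(embedding@coords, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  hdr <- readLines(path, n = 3L)
  field <- function(i, tag) {
    if (!startsWith(hdr[i], paste0("# ", tag, ":")))
      stop("malformed embedding file: missing ", tag, " header")
    strsplit(sub(paste0("^# ", tag, ": ?"), "", hdr[i]), "\t")[[1L]]
  }
  vals <- as.numeric(field(1L, "eigenvalues"))
  dims <- as.integer(field(2L, "imageDim"))
  ndisc <- as.integer(field(3L, "nDiscarded"))
  Y <- as.matrix(utils::read.table(path, sep = "\t", skip = 3L))
  dimnames(Y) <- NULL
  new("ManifoldEmbedding", coords = Y, eigenvalues = vals,
      imageDim = dims, nDiscarded = ndisc)
}

#' Reshape embedding columns into feature images
#'
#' Each embedding coordinate (eigenvector) is reordered into the source
#' image geometry and min-max rescaled to [0, 1]: the structural
#' representation ("feature image") used for mono-modal registration.
#'
#' @param embedding a \linkS4class{ManifoldEmbedding}.
#' @param dim image dimensions \code{c(nr, nc)}; defaults to the
#'   embedding's own.
#' @return list of d matrices in [0, 1].
#' @export
featureImages <- function(embedding, dim = embedding@imageDim) {
  Y <- coords(embedding)
  if (nrow(Y) != prod(dim))
    stop("embedding rows do not match image size")
  lapply(seq_len(ncol(Y)), function(j) {
    col <- Y[, j]
    if (diff(range(col)) < 1e-12 * max(abs(col), 1e-300))
      stop("degenerate embedding column ", j, ": no eigen-structure")
    rescale01(reshapeToImage(col, dim))
  })
}
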