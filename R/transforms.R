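#' Construct a 2-D similarity (or rigid) transform
#'
#' Coordinates are 0-based \code{(x, y) = (column, row)}; the rotation
#' center defaults to the geometric image center
#' \code{((nc - 1) / 2, (nr - 1) / 2)} once an image dimension is known.
#' A point maps as
#' \code{scale * R(theta) (p - center) + center + (tx, ty)}.
#'
#' @param theta rotation angle, radians.
#' @param tx,ty translations, pixels.
#' @param scale isotropic scale (1 = rigid).
#' @param center rotation center (x, y); \code{imageCenter(dim)} is the
#'   conventional choice.
#' @return a \linkS4class{SimilarityTransform2D}.
#' @export
similarityTransform <- function(theta = 0, tx = 0, ty = 0, scale = 1,
                                center = c(0, 0)) {
  new("SimilarityTransform2D", theta = theta, tx = tx, ty = ty,
      scale = scale, center = as.numeric(center))
}

#' @rdname similarityTransform
#' @export
rigidTransform <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0))
  similarityTransform(theta, tx, ty, 1, center)

#' Geometric center of an image, 0-based (x, y)
#' @param dim image dimensions c(nr, nc)
#' @return numeric (x, y) = ((nc - 1) / 2, (nr - 1) / 2)
#' @export
imageCenter <- function(dim) c((dim[2L] - 1) / 2, (dim[1L] - 1) / 2)

#' Homogeneous 3 x 3 matrix of a transform
#' @param t a SimilarityTransform2D
#' @return 3 x 3 matrix acting on column vectors (x, y, 1)'
#' @export
transformMatrix <- function(t) {
  cs <- cos(t@theta); sn <- sin(t@theta)
  A <- t@scale * matrix(c(cs, sn, -sn, cs), 2L, 2L)
  off <- t@center + c(t@tx, t@ty) - A %*% t@center
  rbind(cbind(A, off), c(0, 0, 1))
}

#' Recover a SimilarityTransform2D from a homogeneous matrix
#' @param M 3 x 3 similarity matrix
#' @param center desired rotation center (x, y)
#' @return a SimilarityTransform2D equivalent to M, expressed about center
#' @export
transformFromMatrix <- function(M, center = c(0, 0)) {
  A <- M[1:2, 1:2]
  sc <- sqrt(abs(det(A)))
  if (sc <= 0) stop("matrix is not a similarity (zero scale)")
  th <- atan2(A[2L, 1L], A[1L, 1L])
  tr <- as.numeric(M[1:2, 3L] + A %*% center - center)
  similarityTransform(th, tr[1L], tr[2L], sc, center)
}

#' Compose two transforms (apply a first, then b)
#' @param a,b SimilarityTransform2D objects
#' @param center center for the composed transform (default: b's)
#' @return SimilarityTransform2D equal to b o a
#' @export
composeTransforms <- function(a, b, center = b@center)
  transformFromMatrix(transformMatrix(b) %*% transformMatrix(a), center)

#' Inverse of a transform
#' @param t a SimilarityTransform2D
#' @return SimilarityTransform2D undoing t (same center)
#' @export
invertTransform <- function(t)
  transformFromMatrix(solve(transformMatrix(t)), t@center)

#' Map 0-based (x, y) points through a transform
#' @param t a SimilarityTransform2D
#' @param points n x 2 matrix of (x, y) coordinates
#' @return n x 2 matrix of transformed coordinates
#' @export
transformPoints <- function(t, points) {
  points <- rbind(points)  # accept a bare length-2 vector
  M <- transformMatrix(t)
  out <- cbind(points, 1) %*% t(M)
  out[, 1:2, drop = FALSE]
}

#' Resample an image under a similarity transform
#'
#' Inverse-mapping resampler: output pixel p receives the bilinear
#' interpolation of the input at \code{T^-1(p)}.  Pixels mapping outside
#' the input domain are filled with 0 and reported in the logical
#' \code{"validMask"} attribute of the result.
#'
#' @param image numeric matrix.
#' @param t a \linkS4class{SimilarityTransform2D}.  If its center is
#'   \code{c(0, 0)} and \code{recenter = TRUE} (default) the rotation
#'   center is taken as the image center.
#' @param outDim output dimensions \code{c(nr, nc)}; defaults to input.
#' @param recenter replace a zero center by the image center convention.
#' @return matrix \code{outDim} with attribute \code{validMask}.
#' @export
applyTransform <- function(image, t, outDim = dim(image), recenter = TRUE) {
  if (t@scale <= 0) stop("scale must be positive")
  if (recenter && all(t@center == 0)) {
    t <- similarityTransform(t@theta, t@tx, t@ty, t@scale,
                             imageCenter(dim(image)))
  }
  nrI <- nrow(image); ncI <- ncol(image)
  nrO <- outDim[1L]; ncO <- outDim[2L]
  Minv <- solve(transformMatrix(t))
  xo <- rep(0:(ncO - 1L), each = nrO)
  yo <- rep(0:(nrO - 1L), times = ncO)
  xi <- Minv[1L, 1L] * xo + Minv[1L, 2L] * yo + Minv[1L, 3L]
  yi <- Minv[2L, 1L] * xo + Minv[2L, 2L] * yo + Minv[2L, 3L]
  # tolerate rounding at the exact domain boundary
  eps <- 1e-9 * max(nrI, ncI)
  valid <- xi >= -eps & xi <= ncI - 1L + eps & yi >= -eps & yi <= nrI - 1L + eps
  xi <- pmin(pmax(xi, 0), ncI - 1L); yi <- pmin(pmax(yi, 0), nrI - 1L)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  x0c <- pmin(pmax(x0, 0), ncI - 1L); x1c <- pmin(x0c + 1, ncI - 1L)
  y0c <- pmin(pmax(y0, 0), nrI - 1L); y1c <- pmin(y0c + 1, nrI - 1L)
  at <- function(yy, xx) image[yy + xx * nrI + 1L]
  v <- (1 - fx) * ((1 - fy) * at(y0c, x0c) + fy * at(y1c, x0c)) +
       fx       * ((1 - fy) * at(y0c, x1c) + fy * at(y1c, x1c))
  v[!valid] <- 0
  out <- matrix(v, nrO, ncO)
  attr(out, "validMask") <- matrix(valid, nrO, ncO)
  out
}

#' Validity mask of a resampled image
#' @param image result of \code{\link{applyTransform}}
#' @return logical matrix (TRUE where the source image covered the pixel),
#'   or NULL if absent
#' @export
validMask <- function(image) attr(image, "validMask")
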