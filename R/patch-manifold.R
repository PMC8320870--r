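#' Extract overlapping pixel-centered patches as a point cloud
#'
#' Every pixel of the image contributes the vectorized \code{s x s} patch
#' centered on it (single-pixel stride), so an \code{nr x nc} image becomes
#' \code{N = nr * nc} points in \code{D = s^2} dimensions; a 200 x 200 image
#' with 3 x 3 patches gives a 40,000 x 9 matrix.  Border patches are
#' completed by replicate-edge padding of \code{(s - 1) / 2} pixels, which
#' preserves the intensity range and adds no artificial structure at the
#' boundary.  Rows are in raster order: row \code{(r - 1) * nc + c} is the
#' patch at pixel \code{(r, c)}; within a row, patch pixels are raster
#' ordered too, so the central pixel sits at column \code{(D + 1) / 2}.
#'
#' @param image numeric matrix with finite intensities (conventionally
#'   rescaled to [0, 1], see \code{\link{rescale01}}).
#' @param patchSide odd positive integer patch side, at most
#'   \code{min(dim(image))}.
#' @return a \linkS4class{PatchCloud}.
#' @examples
#' cl <- extractPatches(matrix(runif(64), 8, 8), 3L)
#' dim(cl@points)  # 64 x 9
#' @export
extractPatches <- function(image, patchSide = 3L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (!all(is.finite(image)))
    stop("image intensities must be finite")
  s <- as.integer(patchSide)
  if (length(s) != 1L || is.na(s) || s < 1L || s %% 2L == 0L)
    stop("patchSide must be a single odd positive integer")
  nr <- nrow(image); nc <- ncol(image)
  if (s > min(nr, nc))
    stop("image smaller than patch: need min(dim) >= patchSide")
  h <- (s - 1L) %/% 2L
  pad <- image[c(rep(1L, h), seq_len(nr), rep(nr, h)),
               c(rep(1L, h), seq_len(nc), rep(nc, h)), drop = FALSE]
  N <- nr * nc
  pts <- matrix(0, N, s * s)
  col <- 0L
  for (dr in 0:(s - 1L)) for (dc in 0:(s - 1L)) {
    col <- col + 1L
    # raster (row-major) order over pixels: transpose before flattening
    pts[, col] <- as.vector(t(pad[(1L + dr):(nr + dr),
                                  (1L + dc):(nc + dc), drop = FALSE]))
  }
  # column order within a patch is raster over (dr, dc) as looped above
  new("PatchCloud", points = pts, imageDim = c(nr, nc), patchSide = s)
}

#' Reshape a raster-ordered vector back to image geometry
#'
#' Inverse of the row ordering used by \code{\link{extractPatches}}: entry
#' \code{(r - 1) * nc + c} of the vector lands on pixel \code{(r, c)}.
#' Round-trips exactly with the central-pixel column of the patch matrix.
#'
#' @param vector numeric vector of length \code{nr * nc}.
#' @param dim target image dimensions \code{c(nr, nc)}.
#' @return numeric matrix \code{nr x nc}.
#' @export
reshapeToImage <- function(vector, dim) {
  dim <- as.integer(dim)
  if (length(vector) != prod(dim))
    stop("vector length ", length(vector), " does not match image size ",
         prod(dim))
  matrix(vector, dim[1L], dim[2L], byrow = TRUE)
}

#' Flatten an image to the raster row order of extractPatches
#' @param image numeric matrix
#' @return numeric vector of length nr * nc
#' @export
flattenImage <- function(image) as.vector(t(image))

#' Central-pixel column index of a patch cloud
#' @param cloud a PatchCloud
#' @return integer column index such that
#'   \code{cloud@points[, centerColumn(cloud)]} equals the flattened image
#' @export
centerColumn <- function(cloud) (cloud@patchSide^2 + 1L) %/% 2L
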