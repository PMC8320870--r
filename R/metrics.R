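#' Joint intensity histogram of two images
#'
#' Intensities of each image are binned over that image's own min-max
#' range into \code{bins} equal-width bins; counts are accumulated over
#' all pixels (optionally restricted to a mask, e.g. the valid overlap of
#' a resampled image).
#'
#' @param a,b numeric matrices of equal shape.
#' @param bins number of bins per image (default 50).
#' @param mask optional logical matrix.
#' @return bins x bins integer matrix of counts.
#' @export
jointHistogram <- function(a, b, bins = 50L, mask = NULL) {
  if (!all(dim(a) == dim(b))) stop("images must have equal shapes")
  av <- as.vector(a); bv <- as.vector(b)
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask")
    av <- av[mask]; bv <- bv[mask]
  }
  binOf <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(1L, length(x))
    else pmin(bins, floor((x - rng[1L]) / diff(rng) * bins) + 1L)
  }
  ia <- binOf(av); ib <- binOf(bv)
  counts <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  matrix(counts, bins, bins)
}

#' Histogram mutual information between two images
#'
#' \code{MI = sum p(i, j) log(p(i, j) / (p(i) p(j)))} over the non-empty
#' cells of the 50-bin (by default) joint histogram, in nats.
#'
#' @inheritParams jointHistogram
#' @return mutual information in nats (non-negative).
#' @export
mutualInformation <- function(a, b, bins = 50L, mask = NULL) {
  H <- jointHistogram(a, b, bins, mask)
  p <- H / sum(H)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Marginal (Shannon) entropy of an image's histogram
#' @inheritParams jointHistogram
#' @param x numeric matrix
#' @return entropy in nats
#' @export
imageEntropy <- function(x, bins = 50L, mask = NULL) {
  H <- jointHistogram(x, x, bins, mask)
  p <- rowSums(H) / sum(H)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Landmark mean absolute error between two transforms
#'
#' Mean Euclidean distance between the images of a set of points under the
#' true and the estimated transform, converted to millimetres through the
#' pixel spacing.
#'
#' @param trueT,estT \linkS4class{SimilarityTransform2D}s.
#' @param points n x 2 matrix of 0-based (x, y) landmark coordinates.
#' @param pixelSpacing mm per pixel (default 1: error in pixels).
#' @return scalar mean absolute error (mm).
#' @export
landmarkMAE <- function(trueT, estT, points, pixelSpacing = 1) {
  points <- rbind(points)
  if (nrow(points) < 1L) stop("at least one landmark required")
  pt <- transformPoints(trueT, points)
  pe <- transformPoints(estT, points)
  mean(sqrt(rowSums((pt - pe)^2))) * pixelSpacing
}
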