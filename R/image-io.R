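#' Read a 2-D grayscale image from PNG, TIFF or NIfTI
#'
#' Loads the file, converts to a single-channel floating-point matrix and
#' min-max rescales intensities to [0, 1].  For NIfTI volumes one slice is
#' extracted by index along a chosen anatomical plane.
#'
#' @param path file path; format inferred from the extension
#'   (.png, .tif/.tiff, .nii/.nii.gz).
#' @param slice slice index for volumes (1-based).
#' @param plane slicing plane for volumes: "axial" (third index),
#'   "coronal" (second) or "sagittal" (first).
#' @return numeric matrix (nr x nc) with intensities in [0, 1].
#' @export
readGrayImage <- function(path, slice = 1L,
                          plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.(?=[^.]+$)", "", basename(path), perl = TRUE))
  base <- tolower(basename(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "nii" || grepl("\\.nii\\.gz$", base)) {
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) == 2L) vol
    else switch(plane,
                axial    = vol[, , slice],
                coronal  = vol[, slice, ],
                sagittal = vol[slice, , ])
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3L)                       # collapse channels
    img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  rescale01(img)
}

#' Min-max rescale a matrix to [0, 1]
#'
#' A constant matrix maps to all zeros rather than dividing by zero.
#'
#' @param x numeric matrix with finite entries.
#' @return matrix of the same shape with range [0, 1].
#' @export
rescale01 <- function(x) {
  if (!all(is.finite(x))) stop("image contains non-finite intensities")
  rng <- range(x)
  if (diff(rng) == 0) return(array(0, dim(x)))
  (x - rng[1L]) / diff(rng)
}

#' Resize an image with bilinear interpolation
#'
#' @param image numeric matrix.
#' @param dim target \code{c(nr, nc)}.
#' @return resized matrix, re-clamped to [0, 1] if the input was in range.
#' @export
resizeImage <- function(image, dim) {
  if (all(dim(image) == dim)) return(image)
  out <- EBImage::resize(EBImage::Image(image), w = dim[1L], h = dim[2L])
  m <- EBImage::imageData(out)
  pmin(pmax(m, min(image)), max(image))
}

#' Write a grayscale matrix to PNG
#' @param image matrix in [0, 1]
#' @param path output path
#' @return invisibly, the path
#' @export
writeGrayImage <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
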