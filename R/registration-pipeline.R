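#' Control parameters for the full multi-modal pipeline
#'
#' Defaults follow the registration configuration used throughout the
#' method's experiments: 3 x 3 patches (D = 9), k = 10 symmetric nearest
#' neighbours (k = 20 is the conservative preset for noisy inputs), a
#' 3-dimensional embedding, and the first feature image as the
#' registration channel.
#'
#' @param patchSide odd patch side.
#' @param k neighbour count.
#' @param knnMode "symmetric" or "mutual".
#' @param d embedding dimension.
#' @param featureIndex which aligned feature image drives registration.
#' @param featureScan in partial mode, scan all reference/sensed feature
#'   pairs and keep the candidate with the strongest correlation peak
#'   (eigenvector rank can permute when the sensed field of view is
#'   cropped, so rank pairing alone is unreliable there); disabled in
#'   full mode.
#' @param mode "full" (MSE rigid backend) or "partial" (Fourier-Mellin).
#' @param workingSize optional \code{c(nr, nc)} to resize inputs before
#'   processing (e.g. \code{c(200, 200)}); NULL keeps the input size.
#' @param seed eigensolver seed.
#' @param solverTol,solverMaxiter eigensolver controls.
#' @param rigid list from \code{\link{rigidRegControl}}.
#' @param fmt list from \code{\link{fmtControl}}.
#' @return list of options.
#' @export
multimodalControl <- function(patchSide = 3L, k = 10L, knnMode = "symmetric",
                              d = 3L, featureIndex = 1L, featureScan = TRUE,
                              mode = c("full", "partial"),
                              workingSize = NULL, seed = 1L,
                              solverTol = 1e-9, solverMaxiter = 5000L,
                              rigid = rigidRegControl(),
                              fmt = fmtControl()) {
  list(patchSide = as.integer(patchSide), k = as.integer(k),
       knnMode = knnMode, d = as.integer(d),
       featureIndex = as.integer(featureIndex), featureScan = featureScan,
       mode = match.arg(mode),
       workingSize = workingSize, seed = as.integer(seed),
       solverTol = solverTol, solverMaxiter = as.integer(solverMaxiter),
       rigid = rigid, fmt = fmt)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Multi-modal registration through mono-modal transformation
#'
#' Full pipeline: each input image is independently embedded by the patch
#' Laplacian Eigenmap; the sensed embedding is sign-corrected and rigidly
#' aligned to the reference embedding in feature space; the chosen pair of
#' feature images (reference feature vs aligned sensed feature) is
#' registered with the mono-modal backend selected by \code{mode}; the
#' estimated spatial transform is finally applied to the original sensed
#' image.
#'
#' @param reference,sensed grayscale matrices (min-max rescaled
#'   internally).
#' @param control list from \code{\link{multimodalControl}}.
#' @return a \linkS4class{RegistrationResult} whose \code{details} list
#'   carries \code{registered} (resampled original sensed image),
#'   \code{alignment}, \code{featureRef}, \code{featureSen} (the feature
#'   images used), and \code{backend} (the backend's own result).
#' @export
registerMultimodal <- function(reference, sensed,
                               control = multimodalControl()) {
  cfg <- control
  ref <- rescale01(reference); sen <- rescale01(sensed)
  inDim <- dim(sen)
  if (!is.null(cfg$workingSize)) {
    ref <- resizeImage(ref, cfg$workingSize)
    sen <- resizeImage(sen, cfg$workingSize)
  }
  embR <- .stage("eigenmap/reference",
                 imageEmbedding(ref, cfg$patchSide, cfg$k, cfg$d,
                                cfg$knnMode, seed = cfg$seed,
                                tol = cfg$solverTol,
                                maxiter = cfg$solverMaxiter))
  embS <- .stage("eigenmap/sensed",
                 imageEmbedding(sen, cfg$patchSide, cfg$k, cfg$d,
                                cfg$knnMode, seed = cfg$seed,
                                tol = cfg$solverTol,
                                maxiter = cfg$solverMaxiter))
  ali <- .stage("alignment", alignEmbeddings(embR, embS))
  featR <- .stage("features/reference", featureImages(embR))
  featS <- .stage("features/sensed", alignedFeatureImages(ali))
  fi <- cfg$featureIndex
  if (fi < 1L || fi > length(featR))
    stop("[features] featureIndex out of range")
  back <- .stage("backend", {
    if (cfg$mode == "full") {
      i <- fi; j <- fi
      if (isTRUE(cfg$featureScan)) {
        # eigenvalue crossings between the two manifolds can permute
        # feature rank; pair the registration channel by the strongest
        # absolute pixel correlation and flip an anti-correlated match
        cors <- outer(seq_along(featR), seq_along(featS),
                      Vectorize(function(i, j)
                        stats::cor(as.vector(featR[[i]]),
                                   as.vector(featS[[j]]))))
        pk <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
        i <- pk[1L]; j <- pk[2L]
        if (cors[i, j] < 0) featS[[j]] <- 1 - featS[[j]]
      }
      res <- registerRigid(featR[[i]], featS[[j]], cfg$rigid)
      res@details$featurePair <- c(i, j)
      res
    } else if (!isTRUE(cfg$featureScan)) {
      registerFMT(featR[[fi]], featS[[fi]], cfg$fmt)
    } else {
      # cropping can permute eigenvector rank between the two manifolds;
      # try every feature pairing and keep the strongest correlation peak
      bestRes <- NULL
      for (i in seq_along(featR)) for (j in seq_along(featS)) {
        cand <- registerFMT(featR[[i]], featS[[j]], cfg$fmt)
        if (is.null(bestRes) || cand@metric > bestRes@metric) {
          bestRes <- cand
          bestRes@details$featurePair <- c(i, j)
        }
      }
      bestRes
    }
  })
  # rescale the estimated transform back to the original sensed geometry
  tr <- back@transform
  if (!is.null(cfg$workingSize) && !all(cfg$workingSize == inDim)) {
    fy <- inDim[1L] / cfg$workingSize[1L]
    fx <- inDim[2L] / cfg$workingSize[2L]
    f <- (fx + fy) / 2    # similarity transforms assume isotropic scaling
    tr <- similarityTransform(tr@theta, tr@tx * fx, tr@ty * fy, tr@scale,
                              imageCenter(inDim))
  }
  registered <- .stage("resample",
                       applyTransform(rescale01(sensed), tr,
                                      outDim = dim(reference)))
  new("RegistrationResult", transform = tr, metric = back@metric,
      iterations = back@iterations, converged = back@converged,
      trace = back@trace, method = "pipeline",
      details = list(registered = registered, alignment = ali,
                     featureRef = featR, featureSen = featS,
                     backend = back))
}
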