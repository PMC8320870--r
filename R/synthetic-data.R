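#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so generators are pure
#' functions of their seed arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of expr
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.radiusProfile <- function(phi, r0, amps, phases) {
  r <- rep(r0, length(phi))
  for (m in seq_along(amps))
    r <- r * (1 + amps[m] * cos((m + 1) * phi + phases[m]))
  r
}

#' Generate a structured nested-blob phantom
#'
#' Deterministic (per seed) stand-in for a brain slice: a background plus
#' \code{nStructures} nested, smoothly perturbed elliptical "tissues" with
#' distinct integer labels, slightly offset centers, and 5 landmark points
#' sampled inside the object.  The perturbed boundaries follow
#' \code{r(phi) = r0 prod_m (1 + a_m cos(m phi + psi_m))} with small
#' seeded harmonic amplitudes, giving organ-like asymmetric shapes while
#' keeping the internal structure shared by all simulated modalities.
#'
#' @param shape image dimensions \code{c(nr, nc)}, at least 64 x 64.
#' @param nStructures number of nested structures (>= 1).
#' @param seed integer seed.
#' @param nLandmarks landmark count (default 5).
#' @return a \linkS4class{Phantom}.
#' @export
makePhantom <- function(shape = c(200L, 200L), nStructures = 3L, seed = 1L,
                        nLandmarks = 5L) {
  shape <- as.integer(shape)
  if (any(shape < 64L)) stop("shape must be at least 64 x 64")
  nStructures <- as.integer(nStructures)
  withSeed(seed, {
    nr <- shape[1L]; nc <- shape[2L]
    cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
    X <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
    Y <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
    r0 <- 0.38 * min(nr, nc)
    scales <- r0 * seq(1, 0.35, length.out = nStructures)
    ecc <- stats::runif(1, 0.75, 1)         # ellipse axis ratio
    labels <- matrix(0L, nr, nc)
    for (s in seq_len(nStructures)) {
      ox <- cx + stats::runif(1, -0.04, 0.04) * nc * (s > 1)
      oy <- cy + stats::runif(1, -0.04, 0.04) * nr * (s > 1)
      dx <- (X - ox); dy <- (Y - oy) / ecc
      phi <- atan2(dy, dx)
      rr <- sqrt(dx^2 + dy^2)
      amps <- stats::runif(3, -0.08, 0.08)
      phases <- stats::runif(3, 0, 2 * pi)
      inside <- rr < .radiusProfile(phi, scales[s], amps, phases)
      labels[inside] <- s
    }
    obj <- which(labels > 0L, arr.ind = TRUE)
    pick <- obj[sample.int(nrow(obj), nLandmarks), , drop = FALSE]
    landmarks <- cbind(x = pick[, 2L] - 1, y = pick[, 1L] - 1)
    new("Phantom", image = labels / max(labels, 1L), labels = labels,
        landmarks = landmarks)
  })
}

#' Modality presets: per-tissue intensity lookups
#'
#' Two anatomical-MR-like presets with opposite tissue intensity ordering
#' (emulating the inverted contrast of T1- versus T2-weighted images) and
#' a CT-like preset with compressed soft-tissue contrast.  Noise and bias
#' defaults follow common simulated-MRI settings (3 percent noise, 20
#' percent intensity non-uniformity).
#'
#' @param name "t1", "t2" or "ct".
#' @param nStructures number of non-background tissues to map.
#' @param noiseSigma additive Gaussian noise s.d.
#' @param biasAmplitude multiplicative low-frequency bias amplitude.
#' @param smoothSigma partial-volume blur s.d. (pixels).
#' @return a \linkS4class{ModalityMap}.
#' @export
modalityMap <- function(name = c("t1", "t2", "ct"), nStructures = 3L,
                        noiseSigma = 0.03, biasAmplitude = 0.20,
                        smoothSigma = 0.8) {
  name <- match.arg(name)
  n <- as.integer(nStructures)
  tissue <- switch(name,
    t1 = seq(0.25, 0.9, length.out = n),          # CSF dark -> WM bright
    t2 = seq(0.75, 0.15, length.out = n),         # inverted ordering
    ct = seq(0.45, 0.6, length.out = n))          # compressed contrast
  gamma <- switch(name, t1 = 1, t2 = 0.9, ct = 1.1)
  # the t2-like preset inverts the whole intensity scale (bright
  # surround), so raw-intensity similarity is genuinely anti-correlated
  new("ModalityMap", levels = c(switch(name, t2 = 0.92, ct = 0.1, 0.03),
                                tissue),
      gamma = gamma, noiseSigma = noiseSigma, biasAmplitude = biasAmplitude,
      smoothSigma = smoothSigma, name = name)
}

.biasField <- function(shape) {
  # unit-amplitude smooth field from a few low-order cosine modes
  nr <- shape[1L]; nc <- shape[2L]
  u <- (0:(nr - 1L)) / nr; v <- (0:(nc - 1L)) / nc
  f <- matrix(0, nr, nc)
  for (q in 1:3) {
    f <- f + stats::rnorm(1) *
      outer(cos(pi * q * u + stats::runif(1, 0, 2 * pi)),
            cos(pi * q * v + stats::runif(1, 0, 2 * pi)))
  }
  f / max(abs(f))
}

#' Render a phantom under a modality map
#'
#' Looks up the per-tissue intensity, applies the smooth nonlinearity,
#' Gaussian partial-volume blur, a seeded low-frequency multiplicative
#' bias field and additive Gaussian noise; output clamped to [0, 1].
#' Deterministic per seed.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param map a \linkS4class{ModalityMap}.
#' @param seed integer seed for noise and bias.
#' @return grayscale matrix in [0, 1].
#' @export
simulateModality <- function(phantom, map, seed = 1L) {
  labs <- phantom@labels
  if (max(labs) + 1L > length(map@levels))
    stop("modality map is missing levels for some labels")
  img <- matrix(map@levels[labs + 1L], nrow(labs), ncol(labs))^map@gamma
  withSeed(seed, {
    if (map@smoothSigma > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = map@smoothSigma))
    if (map@biasAmplitude > 0)
      img <- img * (1 + map@biasAmplitude * .biasField(dim(img)))
    if (map@noiseSigma > 0)
      img <- img + matrix(stats::rnorm(length(img), sd = map@noiseSigma),
                          nrow(img))
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a reference/sensed multi-modal pair with known ground truth
#'
#' The reference is the phantom rendered under \code{mapRef}.  The sensed
#' image is the phantom rendered under \code{mapSensed}, warped by a
#' similarity transform sampled from \code{transformSpec} (rotation
#' uniform in [-pi/4, pi/4] by default; translations rejection-sampled so
#' the whole object stays in frame; optional scale), and, when
#' \code{overlapFraction < 1}, cropped so that only that fraction of the
#' warped object area remains visible (remainder set to background).  The
#' stored \code{trueTransform} is the aligning transform (the inverse of
#' the applied warp).  Regeneration from the same seed is bit-identical.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param mapRef,mapSensed \linkS4class{ModalityMap}s.
#' @param transformSpec list with ranges \code{theta}, \code{tx},
#'   \code{ty} (pixels) and \code{scale}; each \code{c(lo, hi)}.
#' @param overlapFraction fraction of the object retained, in (0, 1].
#' @param seed integer seed.
#' @param maxTries rejection-sampling cap for the in-frame constraint.
#' @return a \linkS4class{PhantomPair}.
#' @export
makePair <- function(phantom, mapRef = modalityMap("t1"),
                     mapSensed = modalityMap("t2"),
                     transformSpec = list(theta = c(-pi / 4, pi / 4),
                                          tx = c(-15, 15), ty = c(-15, 15),
                                          scale = c(1, 1)),
                     overlapFraction = 1, seed = 1L, maxTries = 1000L) {
  if (overlapFraction <= 0 || overlapFraction > 1)
    stop("overlapFraction must be in (0, 1]")
  spec <- transformSpec
  for (nm in c("theta", "tx", "ty"))
    if (is.null(spec[[nm]])) spec[[nm]] <- c(0, 0)
  if (is.null(spec$scale)) spec$scale <- c(1, 1)
  reference <- simulateModality(phantom, mapRef, seed)
  sensedFlat <- simulateModality(phantom, mapSensed, seed + 1L)
  dims <- dim(reference)
  mask <- phantom@labels > 0L
  boundary <- which(mask, arr.ind = TRUE)
  boundary <- cbind(x = boundary[, 2L] - 1, y = boundary[, 1L] - 1)
  withSeed(seed + 2L, {
    warp <- NULL
    for (i in seq_len(maxTries)) {
      th <- stats::runif(1, spec$theta[1L], spec$theta[2L])
      sc <- stats::runif(1, spec$scale[1L], spec$scale[2L])
      tx <- stats::runif(1, spec$tx[1L], spec$tx[2L])
      ty <- stats::runif(1, spec$ty[1L], spec$ty[2L])
      cand <- similarityTransform(th, tx, ty, sc, imageCenter(dims))
      pts <- transformPoints(cand, boundary)
      if (all(pts[, 1L] >= 0 & pts[, 1L] <= dims[2L] - 1 &
              pts[, 2L] >= 0 & pts[, 2L] <= dims[1L] - 1)) {
        warp <- cand
        break
      }
    }
    if (is.null(warp))
      stop("could not satisfy the in-frame constraint after ", maxTries,
           " samples; shrink the transform ranges")
    sensed <- applyTransform(sensedFlat, warp, recenter = FALSE)
    # fill out-of-field pixels with the sensed modality's background level
    sensed[!validMask(sensed)] <- mapSensed@levels[1L]^mapSensed@gamma
    attr(sensed, "validMask") <- NULL
    if (overlapFraction < 1) {
      # slide a crop boundary in from a seeded side until the retained
      # fraction of warped object pixels reaches the target
      wmask <- applyTransform(mask + 0, warp, recenter = FALSE) > 0.5
      total <- sum(wmask)
      side <- sample.int(4L, 1L)
      nr <- dims[1L]; nc <- dims[2L]
      keepFrac <- function(cut) {
        kept <- switch(side,
                       sum(wmask[, seq_len(cut)]),        # from left
                       sum(wmask[, (nc - cut + 1L):nc]),  # from right
                       sum(wmask[seq_len(cut), ]),        # from top
                       sum(wmask[(nr - cut + 1L):nr, ]))  # from bottom
        kept / total
      }
      n <- if (side <= 2L) nc else nr
      cut <- which(vapply(seq_len(n), keepFrac, numeric(1L)) >=
                     overlapFraction)[1L]
      keep <- matrix(FALSE, nr, nc)
      switch(side,
             keep[, seq_len(cut)] <- TRUE,
             keep[, (nc - cut + 1L):nc] <- TRUE,
             keep[seq_len(cut), ] <- TRUE,
             keep[(nr - cut + 1L):nr, ] <- TRUE)
      sensed[!keep] <- mapSensed@levels[1L]^mapSensed@gamma
    }
    new("PhantomPair", reference = reference, sensed = sensed,
        trueTransform = invertTransform(warp),
        overlapFraction = overlapFraction,
        landmarks = phantom@landmarks, seed = as.integer(seed))
  })
}
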