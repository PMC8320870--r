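#' Control parameters for Fourier-Mellin registration
#'
#' The rotation/scale stage of the Fourier-Mellin chain is famously
#' sensitive to the spectral content of its inputs; every preprocessing
#' step is therefore a knob.  The defaults are tuned for smooth,
#' piecewise-constant inputs such as Laplacian feature images: a
#' percentile clip removes localized eigenvector spikes, the gradient
#' magnitude (shift/rotation/scale-covariant) restores broadband content,
#' spectral magnitudes are log-compressed, and instead of trusting the
#' single global argmax of the log-polar correlation, the strongest
#' \code{topK} local maxima (and their 180-degree twins) are each verified
#' by the translation-stage correlation peak.
#'
#' @param paddedSize square working size; NULL picks the next power of two
#'   at or above the larger input dimension.
#' @param nAngles rows of the log-polar grid over [0, 180) degrees.
#' @param nRadii log-radius samples.
#' @param highPass apply the Reddy-Chatterji high-pass emphasis to the
#'   spectral magnitudes.
#' @param logMagnitude log-compress spectral magnitudes before log-polar
#'   resampling.
#' @param radialWindow apodize the log-polar maps along the radius before
#'   their phase correlation.
#' @param gradient correlate gradient-magnitude images rather than raw
#'   intensities.
#' @param clipQuantile symmetric percentile clip applied to each input
#'   before anything else (0 disables).
#' @param topK number of log-polar correlation local maxima tried as
#'   (rotation, scale) candidates.
#' @param minPeak translation correlation peak below which the result is
#'   flagged not converged.
#' @param subpixel parabolic interpolation of correlation peaks.
#' @return list of options.
#' @export
fmtControl <- function(paddedSize = NULL, nAngles = 256L, nRadii = 256L,
                       highPass = TRUE, logMagnitude = TRUE,
                       radialWindow = TRUE, gradient = TRUE,
                       clipQuantile = 0.01, topK = 5L, minPeak = 0.03,
                       subpixel = TRUE) {
  list(paddedSize = paddedSize, nAngles = as.integer(nAngles),
       nRadii = as.integer(nRadii), highPass = highPass,
       logMagnitude = logMagnitude, radialWindow = radialWindow,
       gradient = gradient, clipQuantile = clipQuantile,
       topK = as.integer(topK), minPeak = minPeak, subpixel = subpixel)
}

#' @rdname fmtControl
#' @details \code{classicFmtControl} is the textbook chain -- apodize,
#'   high-pass emphasized FFT magnitude, log-polar phase correlation at
#'   its global argmax, de-rotate/de-scale, translation phase correlation
#'   -- with no gradient transform, clipping, log compression, radial
#'   window or multi-candidate search.  It is the appropriate baseline
#'   when asking what plain Fourier-Mellin registration achieves without
#'   the multi-modal to mono-modal transformation; the tuned defaults of
#'   \code{fmtControl} were developed for Laplacian feature images.
#' @export
classicFmtControl <- function(paddedSize = NULL, nAngles = 256L,
                              nRadii = 256L, minPeak = 0.03,
                              subpixel = TRUE) {
  fmtControl(paddedSize = paddedSize, nAngles = nAngles, nRadii = nRadii,
             highPass = TRUE, logMagnitude = FALSE, radialWindow = FALSE,
             gradient = FALSE, clipQuantile = 0, topK = 1L,
             minPeak = minPeak, subpixel = subpixel)
}

.hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

.padSquare <- function(img, S) {
  out <- matrix(0, S, S)
  r0 <- (S - nrow(img)) %/% 2L
  c0 <- (S - ncol(img)) %/% 2L
  out[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))] <- img
  out
}

.fftShift <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2L + 1L):n1, 1L:(n1 %/% 2L)),
    c((n2 %/% 2L + 1L):n2, 1L:(n2 %/% 2L))]
}

.clipRescale <- function(img, p) {
  if (p <= 0) return(rescale01(img))
  q <- stats::quantile(img, c(p, 1 - p), names = FALSE)
  rescale01(pmin(pmax(img, q[1L]), q[2L]))
}

.gradientMagnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]
  gy <- m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]
  sqrt(gx^2 + gy^2)
}

.specMagnitude <- function(img, highPass, logMagnitude) {
  S <- nrow(img)
  w <- .hannWindow(S)
  mag <- .fftShift(Mod(stats::fft(img * outer(w, w))))
  if (highPass) {
    # Reddy-Chatterji emphasis H = (1 - c1 c2)(2 - c1 c2),
    # c_i = cos(pi f_i), f_i in [-1/2, 1/2)
    f <- ((0:(S - 1L)) - S %/% 2L) / S
    cc <- outer(cos(pi * f), cos(pi * f))
    mag <- mag * (1 - cc) * (2 - cc)
  }
  if (logMagnitude) mag <- log1p(mag)
  mag
}

.logPolar <- function(mag, nAngles, nRadii) {
  S <- nrow(mag)
  ctr <- (S %/% 2L)                 # fftShifted DC bin (0-based)
  rmax <- S / 2 - 1
  rmin <- 1
  logstep <- log(rmax / rmin) / nRadii
  r <- rmin * exp((0:(nRadii - 1L)) * logstep)
  a <- (0:(nAngles - 1L)) * pi / nAngles
  X <- ctr + outer(cos(a), r)       # rows = angle, cols = log radius
  Y <- ctr + outer(sin(a), r)
  x0 <- floor(X); y0 <- floor(Y)
  fx <- X - x0; fy <- Y - y0
  ok <- x0 >= 0 & x0 + 1 <= S - 1 & y0 >= 0 & y0 + 1 <= S - 1
  x0 <- pmin(pmax(x0, 0), S - 2); y0 <- pmin(pmax(y0, 0), S - 2)
  at <- function(yy, xx) mag[yy + xx * S + 1L]
  v <- (1 - fx) * ((1 - fy) * at(y0, x0) + fy * at(y0 + 1, x0)) +
       fx       * ((1 - fy) * at(y0, x0 + 1) + fy * at(y0 + 1, x0 + 1))
  v[!ok] <- 0
  list(lp = matrix(v, nAngles, nRadii), logstep = logstep)
}

.pcSurface <- function(a, b) {
  # normalized cross-power spectrum; the inverse FFT peaks (cyclically) at
  # the d with a(x) ~ b(x + d): translating b by +d aligns it with a
  cp <- stats::fft(a) * Conj(stats::fft(b))
  cp <- cp / pmax(Mod(cp), 1e-12)
  Re(stats::fft(cp, inverse = TRUE)) / length(a)
}

.subpixelAt <- function(corr, r, c, subpixel = TRUE) {
  # cyclic 3-point parabola around 0-based integer location (r, c)
  n1 <- nrow(corr); n2 <- ncol(corr)
  v <- corr[r + 1L, c + 1L]
  if (!subpixel) return(list(dr = r, dc = c, value = v))
  para <- function(y0, y1, y2) {
    den <- y0 - 2 * y1 + y2
    if (den == 0) 0 else 0.5 * (y0 - y2) / den
  }
  dr <- r + para(corr[(r - 1L) %% n1 + 1L, c + 1L], v,
                 corr[(r + 1L) %% n1 + 1L, c + 1L])
  dc <- c + para(corr[r + 1L, (c - 1L) %% n2 + 1L], v,
                 corr[r + 1L, (c + 1L) %% n2 + 1L])
  list(dr = dr, dc = dc, value = v)
}

.wrapShift <- function(d, n) if (d > n / 2) d - n else d

.phaseCorrelate <- function(a, b, subpixel = TRUE) {
  corr <- .pcSurface(a, b)
  pk <- which.max(corr)
  r <- (pk - 1L) %% nrow(a)
  c <- (pk - 1L) %/% nrow(a)
  sp <- .subpixelAt(corr, r, c, subpixel)
  list(shift = c(.wrapShift(sp$dr, nrow(a)), .wrapShift(sp$dc, ncol(a))),
       peak = sp$value)
}

.localMaxima <- function(corr, K) {
  n1 <- nrow(corr); n2 <- ncol(corr)
  sh <- function(dr, dc) corr[(0:(n1 - 1L) + dr) %% n1 + 1L,
                              (0:(n2 - 1L) + dc) %% n2 + 1L]
  ismax <- corr >= sh(1, 0) & corr >= sh(-1, 0) &
           corr >= sh(0, 1) & corr >= sh(0, -1) &
           corr >= sh(1, 1) & corr >= sh(-1, -1) &
           corr >= sh(1, -1) & corr >= sh(-1, 1)
  idx <- which(ismax)
  idx <- idx[order(corr[idx], decreasing = TRUE)]
  idx[seq_len(min(K, length(idx)))]
}

#' Fourier-Mellin similarity registration (partial-overlap backend)
#'
#' Classic Fourier-Mellin chain: both images are (optionally clipped,
#' gradient-transformed and) zero-padded to a common square and apodized
#' with a raised-cosine window; the fftshifted FFT magnitudes (high-pass
#' emphasized, log-compressed) are resampled onto a log-polar grid; phase
#' correlation there yields rotation and scale candidates -- the strongest
#' \code{topK} local maxima, each with its 180-degree twin (the magnitude
#' spectrum cannot distinguish a rotation from its half-turn).  Every
#' candidate is applied to the sensed image and scored by the peak of the
#' final translation phase correlation against the reference; the winner
#' supplies rotation, scale and (subpixel) translation.  A winning peak
#' below \code{minPeak} flags the result not converged.
#'
#' @param reference,sensed numeric matrices (any shapes).
#' @param control list from \code{\link{fmtControl}}.
#' @return a \linkS4class{RegistrationResult}; the transform maps the
#'   sensed image onto the reference, and \code{metric} holds the winning
#'   translation correlation peak.
#' @export
registerFMT <- function(reference, sensed, control = fmtControl()) {
  ctrl <- control
  ref <- .clipRescale(reference, ctrl$clipQuantile)
  sen <- .clipRescale(sensed, ctrl$clipQuantile)
  if (ctrl$gradient) {
    ref <- .gradientMagnitude(ref)
    sen <- .gradientMagnitude(sen)
  }
  S <- ctrl$paddedSize
  if (is.null(S)) S <- 2^ceiling(log2(max(dim(ref), dim(sen))))
  refP <- .padSquare(ref, S)
  senP <- .padSquare(sen, S)
  lpR <- .logPolar(.specMagnitude(refP, ctrl$highPass, ctrl$logMagnitude),
                   ctrl$nAngles, ctrl$nRadii)
  lpS <- .logPolar(.specMagnitude(senP, ctrl$highPass, ctrl$logMagnitude),
                   ctrl$nAngles, ctrl$nRadii)
  a <- lpR$lp; b <- lpS$lp
  if (ctrl$radialWindow) {
    w <- .hannWindow(ctrl$nRadii)
    a <- sweep(a, 2L, w, `*`); b <- sweep(b, 2L, w, `*`)
  }
  corr <- .pcSurface(a, b)
  ctr <- imageCenter(c(S, S))
  win <- outer(.hannWindow(S), .hannWindow(S))
  refW <- refP * win
  best <- NULL
  for (pk in .localMaxima(corr, ctrl$topK)) {
    r <- (pk - 1L) %% ctrl$nAngles
    cidx <- (pk - 1L) %/% ctrl$nAngles
    sp <- .subpixelAt(corr, r, cidx, ctrl$subpixel)
    dr <- .wrapShift(sp$dr, ctrl$nAngles)
    dc <- .wrapShift(sp$dc, ctrl$nRadii)
    # angle rows run counter to the image-domain rotation sense (y points
    # down in pixel coordinates), hence the sign
    rot <- -dr * pi / ctrl$nAngles    # sensed is ref rotated by rot ...
    sc <- exp(dc * lpR$logstep)       # ... and scaled by sc
    for (th in c(rot, rot + pi)) {
      cand <- similarityTransform(-th, 0, 0, 1 / sc, ctr)
      corrected <- applyTransform(senP, cand, recenter = FALSE)
      tpc <- .phaseCorrelate(refW, corrected * win, ctrl$subpixel)
      if (is.null(best) || tpc$peak > best$peak)
        best <- list(theta = -th, sc = sc, peak = tpc$peak,
                     shift = tpc$shift)
    }
  }
  # the corrected image matches the reference when translated by
  # +(dx, dy) = +(shift[2], shift[1])
  final <- composeTransforms(
    similarityTransform(best$theta, 0, 0, 1 / best$sc, ctr),
    similarityTransform(0, best$shift[2L], best$shift[1L], 1, ctr))
  # express about the unpadded sensed-image center: padding centered both
  # images, so the same map applies between offset frames
  offS <- c((S - ncol(sensed)) %/% 2L, (S - nrow(sensed)) %/% 2L)
  offR <- c((S - ncol(reference)) %/% 2L, (S - nrow(reference)) %/% 2L)
  M <- rbind(cbind(diag(2), -offR), c(0, 0, 1)) %*%
    transformMatrix(final) %*% rbind(cbind(diag(2), offS), c(0, 0, 1))
  tr <- transformFromMatrix(M, imageCenter(dim(sensed)))
  new("RegistrationResult", transform = tr, metric = best$peak,
      iterations = 0L, converged = best$peak >= ctrl$minPeak,
      trace = best$peak, method = "fmt",
      details = list(scale = best$sc, rotation = best$theta,
                     peak = best$peak))
}
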