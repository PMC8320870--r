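#' Mean-squared-error metric between two images
#'
#' @param a,b numeric matrices of equal shape.
#' @param mask optional logical matrix restricting the average.
#' @return mean of squared intensity differences.
#' @export
mseMetric <- function(a, b, mask = NULL) {
  if (!all(dim(a) == dim(b))) stop("images must have equal shapes")
  d2 <- (a - b)^2
  if (is.null(mask)) mean(d2)
  else {
    if (!any(mask)) stop("empty mask")
    mean(d2[mask])
  }
}

#' Control parameters for rigid MSE registration
#'
#' Regular-step gradient descent over (theta, tx, ty) wrapped in a
#' multiresolution pyramid.  The angle is handled in degrees internally so
#' one optimizer unit moves the image periphery by roughly one pixel,
#' matching the pixel units of the translations.
#'
#' @param levels pyramid levels (coarsest is 1 / 2^(levels-1) scale).
#' @param initStep initial step length, optimizer units (deg / px).
#' @param minStep step length below which the level terminates.
#' @param relaxation step multiplier on gradient direction reversal.
#' @param maxIter iteration cap per level.
#' @param gradDelta central-difference probe, optimizer units.
#' @param metricTol relative metric improvement below which a step counts
#'   as stalled (shrinks the step like a gradient reversal).
#' @param initAngles coarse-level rotation grid for initialization
#'   (degrees); NULL disables the grid search.
#' @return list of class options.
#' @export
rigidRegControl <- function(levels = 3L, initStep = 2, minStep = 1e-4,
                            relaxation = 0.5, maxIter = 300L,
                            gradDelta = 0.1, metricTol = 1e-6,
                            initAngles = seq(-48, 48, by = 6)) {
  list(levels = as.integer(levels), initStep = initStep, minStep = minStep,
       relaxation = relaxation, maxIter = as.integer(maxIter),
       gradDelta = gradDelta, metricTol = metricTol,
       initAngles = initAngles)
}

.halveImage <- function(img) {
  EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                     w = max(1L, nrow(img) %/% 2L),
                                     h = max(1L, ncol(img) %/% 2L)))
}

.rigidMse <- function(p, ref, sen) {
  # p = (theta deg, tx, ty); masked MSE of warped sensed vs reference
  w <- applyTransform(sen, rigidTransform(p[1L] * pi / 180, p[2L], p[3L],
                                          imageCenter(dim(sen))),
                      outDim = dim(ref), recenter = FALSE)
  m <- validMask(w)
  if (!any(m)) return(1e3)   # finite penalty: no overlap at this pose
  mseMetric(ref, w, m)
}

.regularStepDescent <- function(f, p0, ctrl) {
  # fixed-length step along the negative normalized gradient; the step
  # shrinks by the relaxation factor on a gradient direction reversal and
  # when a step fails to improve the metric (monotone safeguard), and the
  # level terminates once it falls below minStep
  p <- p0
  fcur <- f(p)
  trace <- fcur
  step <- ctrl$initStep
  gprev <- NULL
  iter <- 0L
  h <- ctrl$gradDelta
  while (iter < ctrl$maxIter && step >= ctrl$minStep) {
    iter <- iter + 1L
    g <- vapply(seq_along(p), function(i) {
      e <- replace(numeric(length(p)), i, h)
      (f(p + e) - f(p - e)) / (2 * h)
    }, numeric(1L))
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn)) stop("non-finite metric gradient at ",
                             paste(signif(p, 6), collapse = ", "))
    if (gn == 0) break
    pn <- p - step * g / gn
    fn <- f(pn)
    trace <- c(trace, fn)
    if (fn < fcur) {
      # shrink on direction reversal and on vanishing improvement
      # (zigzag through a narrow valley reverses slowly but stalls)
      if ((!is.null(gprev) && sum(g * gprev) < 0) ||
          fcur - fn < ctrl$metricTol * (abs(fcur) + 1e-12))
        step <- step * ctrl$relaxation
      gprev <- g
      p <- pn
      fcur <- fn
    } else {
      step <- step * ctrl$relaxation
    }
  }
  list(par = p, value = fcur, iterations = iter, trace = trace,
       converged = step < ctrl$minStep)
}

#' Rigid registration by MSE and regular-step gradient descent
#'
#' Estimates the rigid transform (rotation + translation about the image
#' center) that maps the sensed image onto the reference by minimizing the
#' masked mean-squared error.  A 3-level multiresolution pyramid extends
#' the capture range; at the coarsest level the translation is initialized
#' from the intensity-centroid offset and the rotation from a coarse grid
#' search.  The optimizer steps a fixed length along the negative
#' normalized gradient (central differences) and halves the step whenever
#' the gradient direction reverses, stopping below \code{minStep}.
#'
#' @param reference,sensed numeric matrices of equal shape (typically the
#'   first aligned feature images of the two modalities).
#' @param control list from \code{\link{rigidRegControl}}.
#' @return a \linkS4class{RegistrationResult} with a rigid transform.
#' @export
registerRigid <- function(reference, sensed, control = rigidRegControl()) {
  if (!all(dim(reference) == dim(sensed)))
    stop("reference and sensed must have equal shapes")
  ctrl <- control
  pyrR <- list(reference); pyrS <- list(sensed)
  for (l in seq_len(ctrl$levels - 1L)) {
    pyrR <- c(list(.halveImage(pyrR[[1L]])), pyrR)
    pyrS <- c(list(.halveImage(pyrS[[1L]])), pyrS)
  }
  # coarse initialization: intensity centroids for translation, grid for
  # rotation
  refC <- pyrR[[1L]]; senC <- pyrS[[1L]]
  cm <- function(img) {
    w <- pmax(img - stats::median(img), 0); sw <- sum(w)
    if (sw == 0) return(imageCenter(dim(img)))
    c(sum(w * col(img) - w) / sw, sum(w * row(img) - w) / sw)
  }
  t0 <- cm(refC) - cm(senC)
  starts <- list(c(0, t0[1L], t0[2L]))
  if (!is.null(ctrl$initAngles) && length(ctrl$initAngles) > 1L) {
    # each candidate angle gets its own translation from a coarse phase
    # correlation (the MSE landscape over rotation is deceptive at a
    # fixed translation); descent then starts from the best few poses
    cand <- lapply(ctrl$initAngles, function(a) {
      rot <- applyTransform(senC, rigidTransform(a * pi / 180, 0, 0,
                                                 imageCenter(dim(senC))),
                            outDim = dim(refC), recenter = FALSE)
      pc <- .phaseCorrelate(refC, matrix(rot, nrow(rot)), subpixel = FALSE)
      c(a, pc$shift[2L], pc$shift[1L])
    })
    vals <- vapply(cand, function(p) .rigidMse(p, refC, senC), numeric(1L))
    starts <- cand[order(vals)[seq_len(min(3L, length(cand)))]]
  }
  iterations <- 0L
  coarse <- NULL
  cctrl <- ctrl
  cctrl$maxIter <- min(ctrl$maxIter, 100L)   # multi-starts stay cheap
  for (p0 in starts) {
    lev <- .regularStepDescent(function(q) .rigidMse(q, pyrR[[1L]],
                                                     pyrS[[1L]]),
                               p0, cctrl)
    iterations <- iterations + lev$iterations
    if (is.null(coarse) || lev$value < coarse$value) coarse <- lev
  }
  p <- coarse$par
  trace <- coarse$trace
  value <- coarse$value
  converged <- TRUE
  for (l in seq_along(pyrR)[-1L]) {
    p[2L] <- p[2L] * 2; p[3L] <- p[3L] * 2
    # finer levels only refine: restart them with a proportionally
    # smaller step so the anneal to minStep completes within the cap
    lctrl <- ctrl
    lctrl$initStep <- ctrl$initStep / 2^(l - 1L)
    lev <- .regularStepDescent(function(q) .rigidMse(q, pyrR[[l]], pyrS[[l]]),
                               p, lctrl)
    p <- lev$par
    iterations <- iterations + lev$iterations
    trace <- c(trace, lev$trace)
    # convergence is judged by the refinement levels completing their
    # step anneal; capped coarse multi-starts are initialization only
    converged <- converged && lev$converged
    value <- lev$value
  }
  tr <- rigidTransform(p[1L] * pi / 180, p[2L], p[3L],
                       imageCenter(dim(sensed)))
  new("RegistrationResult", transform = tr, metric = value,
      iterations = as.integer(iterations), converged = converged,
      trace = trace, method = "rigid", details = list())
}
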