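test_that("MSE metric matches closed forms and a naive loop oracle", {
  a <- matrix(runif(60), 6, 10)
  expect_equal(mseMetric(a, a), 0)
  expect_equal(mseMetric(a, a + 0.5), 0.25)
  b <- matrix(runif(60), 6, 10)
  expect_equal(mseMetric(a, b), naiveMse(a, b), tolerance = 1e-12)
  m <- matrix(FALSE, 6, 10); m[1:3, 1:5] <- TRUE
  expect_equal(mseMetric(a, b, m), naiveMse(a[1:3, 1:5], b[1:3, 1:5]),
               tolerance = 1e-12)
  expect_error(mseMetric(a, t(b)), "equal shapes")
  expect_error(mseMetric(a, b, matrix(FALSE, 6, 10)), "empty mask")
})

test_that("similarity transforms compose, invert and report parameters", {
  t1 <- similarityTransform(0.4, 3, -2, 1.3, c(10, 15))
  t2 <- invertTransform(t1)
  id <- composeTransforms(t1, t2)
  expect_equal(parameters(id), c(theta = 0, tx = 0, ty = 0, scale = 1),
               tolerance = 1e-12)
  # composition agrees with matrix multiplication on points
  t3 <- similarityTransform(-0.2, 1, 4, 0.9, c(10, 15))
  pts <- matrix(runif(10, 0, 30), 5, 2)
  expect_equal(transformPoints(composeTransforms(t1, t3), pts),
               transformPoints(t3, transformPoints(t1, pts)),
               tolerance = 1e-10)
  expect_error(similarityTransform(scale = -1), "positive")
})

test_that("resampling under a transform round-trips and matches exact rotations", {
  img <- texturedImage(64, seed = 41)
  expect_equal(applyTransform(img, rigidTransform(0, 0, 0)), img,
               ignore_attr = TRUE)
  # integer translate then inverse-translate: interior pixels exact
  tt <- rigidTransform(0, 7, -4)
  w <- applyTransform(img, tt)
  b <- applyTransform(w, invertTransform(
    rigidTransform(0, 7, -4, imageCenter(dim(img)))), recenter = FALSE)
  inner <- 9:56
  expect_lt(max(abs(b[inner, inner] - img[inner, inner])), 1e-6)
  # 90-degree rotation of a square image equals the exact array rotation
  r90 <- applyTransform(img, rigidTransform(pi / 2, 0, 0))
  expect_equal(r90, t(img[nrow(img):1, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # out-of-domain pixels are zero-filled and flagged
  sh <- applyTransform(img, rigidTransform(0, 10, 0))
  expect_true(all(sh[, 1:9] == 0))
  expect_false(any(validMask(sh)[, 1:9]))
})

test_that("rigid registration recovers constructed transforms", {
  ph <- makePhantom(c(128, 128), 3, seed = 3)
  img <- simulateModality(ph, modalityMap("t1"), 5)
  # identity pair
  r0 <- registerRigid(img, img)
  p0 <- parameters(r0@transform)
  expect_lt(abs(p0["theta"]), 0.01)
  expect_lt(max(abs(p0[c("tx", "ty")])), 0.5)
  # pure translation by (7, -4)
  sen <- applyTransform(img, rigidTransform(0, 7, -4))
  attr(sen, "validMask") <- NULL
  r1 <- registerRigid(img, sen)
  expect_equal(unname(parameters(r1@transform)[c("tx", "ty")]), c(-7, 4),
               tolerance = 0.5)
  # rotation 15 degrees plus shift (5, 3), multiresolution on
  tt <- rigidTransform(15 * pi / 180, 5, 3, imageCenter(dim(img)))
  sen2 <- applyTransform(img, tt, recenter = FALSE)
  attr(sen2, "validMask") <- NULL
  r2 <- registerRigid(img, sen2)
  truth <- parameters(invertTransform(tt))
  est <- parameters(r2@transform)
  expect_lt(abs(est["theta"] - truth["theta"]), pi / 180)
  expect_lt(max(abs(est[c("tx", "ty")] - truth[c("tx", "ty")])), 0.5)
  expect_true(all(is.finite(r2@trace)))
})

test_that("Fourier-Mellin registration handles identity and exact integer shifts", {
  ph <- makePhantom(c(128, 128), 3, seed = 3)
  img <- simulateModality(ph, modalityMap("t1"), 5)
  r0 <- registerFMT(img, img)
  p0 <- parameters(r0@transform)
  expect_equal(unname(p0), c(0, 0, 0, 1), tolerance = 1e-6)
  expect_gt(r0@metric, 0.99)
  # FFT shift theorem: pure integer translation recovered exactly
  sen <- applyTransform(img, rigidTransform(0, 12, -9))
  attr(sen, "validMask") <- NULL
  r1 <- registerFMT(img, sen)
  p1 <- parameters(r1@transform)
  expect_equal(unname(p1[c("tx", "ty")]), c(-12, 9), tolerance = 0.05)
  expect_lt(abs(p1["theta"]), 1e-3)
  expect_equal(unname(p1["scale"]), 1, tolerance = 1e-3)
  # same under the classic textbook chain
  rc <- registerFMT(img, sen, classicFmtControl())
  expect_equal(unname(parameters(rc@transform)[c("tx", "ty")]), c(-12, 9),
               tolerance = 0.05)
})

test_that("Fourier-Mellin recovers rotation, scale and crop", {
  ph <- makePhantom(c(200, 200), 3, seed = 1)
  img <- simulateModality(ph, modalityMap("t1"), 5)
  tt <- similarityTransform(25 * pi / 180, 6, -5, 1.3,
                            imageCenter(dim(img)))
  sen <- applyTransform(img, tt, recenter = FALSE)
  attr(sen, "validMask") <- NULL
  sen[, 121:200] <- as.numeric(quantile(img, 0.05))   # keep 60 percent
  r <- registerFMT(img, sen)
  truth <- parameters(invertTransform(tt))
  est <- parameters(r@transform)
  expect_lt(abs(est["scale"] - truth["scale"]) / truth["scale"], 0.03)
  expect_lt(abs(est["theta"] - truth["theta"]), pi / 180)
  expect_lt(max(abs(est[c("tx", "ty")] - truth[c("tx", "ty")])), 2)
  expect_true(r@converged)
})

test_that("multi-modal pipeline aligns a full-overlap pair end to end", {
  ph <- makePhantom(c(128, 128), 3, seed = 51)
  pair <- makePair(ph, modalityMap("t1"), modalityMap("t2"),
                   transformSpec = list(theta = c(-pi / 6, pi / 6),
                                        tx = c(-8, 8), ty = c(-8, 8)),
                   seed = 51)
  res <- registerMultimodal(pair@reference, pair@sensed)
  mae <- landmarkMAE(pair@trueTransform, res@transform, pair@landmarks)
  expect_lt(mae, 2)
  reg <- res@details$registered
  expect_gt(mutualInformation(pair@reference, reg, mask = validMask(reg)),
            mutualInformation(pair@reference, pair@sensed))
  # identical mono-modal inputs give a near-identity transform
  resId <- registerMultimodal(pair@reference, pair@reference)
  pid <- parameters(resId@transform)
  expect_lt(abs(pid["theta"]), 0.01)
  expect_lt(max(abs(pid[c("tx", "ty")])), 0.5)
})
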