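test_that("phantom generation is deterministic and structured", {
  p1 <- makePhantom(c(96, 96), 3L, seed = 7)
  p2 <- makePhantom(c(96, 96), 3L, seed = 7)
  expect_identical(p1@labels, p2@labels)
  expect_identical(p1@landmarks, p2@landmarks)
  expect_setequal(unique(as.vector(p1@labels)), 0:3)
  expect_identical(nrow(p1@landmarks), 5L)
  # landmarks sit inside the object
  for (i in 1:5)
    expect_gt(p1@labels[p1@landmarks[i, 2] + 1, p1@landmarks[i, 1] + 1], 0)
  expect_error(makePhantom(c(32, 32)), "at least 64")
  expect_false(identical(makePhantom(c(96, 96), seed = 8)@labels, p1@labels))
})

test_that("modality presets invert tissue ordering and stay anti-correlated", {
  ph <- makePhantom(c(96, 96), 3L, seed = 3)
  t1 <- simulateModality(ph, modalityMap("t1"), 1)
  t2 <- simulateModality(ph, modalityMap("t2"), 2)
  m1 <- vapply(1:3, function(l) mean(t1[ph@labels == l]), numeric(1))
  m2 <- vapply(1:3, function(l) mean(t2[ph@labels == l]), numeric(1))
  expect_identical(order(m1), rev(order(m2)))    # opposite rank order
  expect_lt(cor(as.vector(t1), as.vector(t2)), 0)
  # statistically dependent despite the anti-correlation (the ratio to
  # self-MI sits near 0.28 under 3 percent noise with 50 bins; noise
  # inflates the marginal-entropy denominator)
  expect_gt(mutualInformation(t1, t2), 0.25 * mutualInformation(t1, t1))
  # noise-free identity lookup reproduces the label intensities
  flat <- modalityMap("t1", noiseSigma = 0, biasAmplitude = 0,
                      smoothSigma = 0)
  img <- simulateModality(ph, flat, 1)
  expect_equal(sort(unique(as.vector(img))), sort(unique(flat@levels)))
  expect_identical(simulateModality(ph, modalityMap("t1"), 9),
                   simulateModality(ph, modalityMap("t1"), 9))
})

test_that("pair generation respects the transform spec and stays in frame", {
  ph <- makePhantom(c(128, 128), 3L, seed = 5)
  # identity spec: sensed differs only by modality and noise
  pid <- makePair(ph, modalityMap("t1"), modalityMap("t2"),
                  transformSpec = list(theta = c(0, 0), tx = c(0, 0),
                                       ty = c(0, 0)), seed = 5)
  expect_equal(parameters(pid@trueTransform),
               c(theta = 0, tx = 0, ty = 0, scale = 1), tolerance = 1e-12)
  expect_identical(pid@sensed,
                   makePair(ph, modalityMap("t1"), modalityMap("t2"),
                            transformSpec = list(theta = c(0, 0),
                                                 tx = c(0, 0),
                                                 ty = c(0, 0)),
                            seed = 5)@sensed)
  # batch of sampled pairs: rotations in range, object bounding box in frame
  mask <- ph@labels > 0
  pix <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = pix[, 2] - 1, y = pix[, 1] - 1)
  for (sd in 1:30) {
    pr <- makePair(ph, modalityMap("t1"), modalityMap("t2"), seed = sd)
    warp <- invertTransform(pr@trueTransform)
    expect_lte(abs(warp@theta), pi / 4 + 1e-12)
    moved <- transformPoints(warp, pts)
    expect_true(all(moved[, 1] >= 0 & moved[, 1] <= 127 &
                      moved[, 2] >= 0 & moved[, 2] <= 127))
  }
  expect_error(makePair(ph, overlapFraction = 0), "overlapFraction")
})

test_that("seeded pairs regenerate bit-identically including the transform", {
  ph <- makePhantom(c(96, 96), 3L, seed = 2)
  a <- makePair(ph, modalityMap("t1"), modalityMap("t2"), seed = 42,
                overlapFraction = 0.7)
  b <- makePair(ph, modalityMap("t1"), modalityMap("t2"), seed = 42,
                overlapFraction = 0.7)
  expect_identical(a@reference, b@reference)
  expect_identical(a@sensed, b@sensed)
  expect_identical(parameters(a@trueTransform), parameters(b@trueTransform))
  # partial overlap blanks part of the frame relative to the full pair
  full <- makePair(ph, modalityMap("t1"), modalityMap("t2"), seed = 42)
  expect_gt(sum(a@sensed != full@sensed), 0)
})
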