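# rotation matrices for the construction oracles
rotX <- function(t) rbind(c(1, 0, 0), c(0, cos(t), -sin(t)),
                          c(0, sin(t), cos(t)))
rotZ <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))

anisoCloud <- function(n = 400, seed = 1)
  withr::with_seed(seed, matrix(rnorm(n * 3), n) %*% diag(c(3, 2, 1)))

test_that("principal frame matches a brute-force covariance eigendecomposition", {
  Y <- anisoCloud(seed = 11)
  fr <- principalFrame(Y)
  # oracle: explicit covariance sum and dense eigendecomposition
  Yc <- sweep(Y, 2, colMeans(Y))
  V <- matrix(0, 3, 3)
  for (i in seq_len(nrow(Y))) V <- V + tcrossprod(Yc[i, ])
  V <- V / nrow(Y)
  ev <- eigen(V, symmetric = TRUE)
  expect_equal(fr@variances, ev$values, tolerance = 1e-12)
  expect_equal(abs(crossprod(fr@directions, ev$vectors)), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(fr@directions), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_false(is.unsorted(rev(fr@variances)))
})

test_that("degenerate point configurations give deterministic frames", {
  # points on the x-axis: first direction (+-1, 0), second variance 0
  Y <- cbind(seq(-2, 2, length.out = 20), 0)
  expect_warning(fr <- principalFrame(Y), "rank-deficient")
  expect_equal(abs(fr@directions[, 1]), c(1, 0), tolerance = 1e-12)
  expect_equal(fr@variances[2], 0, tolerance = 1e-12)
  # points on the 45-degree line
  Yd <- cbind(seq_len(30), seq_len(30) + 0)
  expect_warning(fd <- principalFrame(Yd))
  expect_equal(fd@directions[, 1], c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("sign correction recovers arbitrary reflection patterns", {
  Y <- anisoCloud(seed = 21)
  sc <- signCorrect(Y, Y)
  expect_equal(sc$signFlips, rep(1, 3))
  flipped <- sweep(Y, 2, c(1, -1, 1), `*`)
  sc2 <- signCorrect(Y, flipped)
  expect_equal(sc2$signFlips, c(1, -1, 1))
  expect_equal(sc2$coords, Y)
  # property: 100 random patterns, always recovered exactly
  withr::with_seed(33, {
    for (i in 1:100) {
      s <- sample(c(-1, 1), 3, replace = TRUE)
      got <- signCorrect(Y, sweep(Y, 2, s, `*`))
      expect_equal(got$signFlips, s)
    }
  })
  expect_error(signCorrect(Y, Y[, 1:2]), "agree")
})

test_that("self-alignment is the identity", {
  Y <- anisoCloud(seed = 5)
  a <- alignEmbeddings(Y, Y)
  expect_equal(a@rotation, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(coords(a), Y, tolerance = 1e-12)
  expect_equal(a@signFlips, rep(1, 3))
})

test_that("alignment recovers a known rotation about the centroid", {
  Y <- anisoCloud(seed = 7)
  Q <- rotZ(0.35) %*% rotX(-0.25)
  ctr <- colMeans(Y)
  S <- sweep(sweep(Y, 2, ctr) %*% t(Q), 2, ctr, `+`)
  a <- alignEmbeddings(Y, S)
  expect_equal(a@rotation, t(Q), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(coords(a), Y, tolerance = 1e-6)
  expect_equal(det(a@rotation), 1, tolerance = 1e-10)
})

test_that("axis negation composed with a rotation is still recovered", {
  Y <- anisoCloud(seed = 13)
  Q <- rotZ(-0.3) %*% rotX(0.2)
  ctr <- colMeans(Y)
  # negate an axis first (eigenvector reflection), then rotate the cloud
  Yneg <- sweep(Y, 2, c(1, -1, 1), `*`)
  ctrN <- colMeans(Yneg)
  S <- sweep(sweep(Yneg, 2, ctrN) %*% t(Q), 2, ctrN, `+`)
  a <- alignEmbeddings(Y, S)
  expect_equal(coords(a), Y, tolerance = 1e-6)
  expect_lt(max(abs(crossprod(a@rotation) - diag(3))), 1e-8)
})

test_that("rotation orthonormality holds across random alignment runs", {
  withr::with_seed(17, {
    for (i in 1:20) {
      Y <- matrix(rnorm(200 * 3), 200) %*% diag(runif(3, 0.5, 3))
      Q <- rotZ(runif(1, -0.5, 0.5)) %*% rotX(runif(1, -0.5, 0.5))
      S <- Y %*% t(Q)
      a <- alignEmbeddings(Y, S)
      expect_lt(max(abs(crossprod(a@rotation) - diag(3))), 1e-8)
      expect_gt(det(a@rotation), 0)
    }
  })
})

test_that("aligned feature images are invariant to sensed column negation", {
  img <- texturedImage(28, seed = 9)
  emb <- imageEmbedding(img, k = 8L, d = 3L)
  embFlip <- emb
  embFlip@coords <- sweep(emb@coords, 2, c(-1, 1, -1), `*`)
  f0 <- alignedFeatureImages(alignEmbeddings(emb, emb))
  f1 <- alignedFeatureImages(alignEmbeddings(emb, embFlip))
  for (j in 1:3) expect_equal(f0[[j]], f1[[j]], tolerance = 1e-9)
  # identity alignment reproduces the embedding's own feature images
  fs <- featureImages(emb)
  for (j in 1:3) expect_equal(f0[[j]], fs[[j]], tolerance = 1e-9)
})

test_that("alignment brings the two modality feature images closer than raw images", {
  ph <- makePhantom(c(96, 96), 3, seed = 31)
  a <- simulateModality(ph, modalityMap("t1"), 1)
  b <- simulateModality(ph, modalityMap("t2"), 2)
  embA <- imageEmbedding(a)
  embB <- imageEmbedding(b)
  ali <- alignEmbeddings(embA, embB)
  fA <- featureImages(embA)[[1]]
  fB <- alignedFeatureImages(ali)[[1]]
  expect_lt(mean(abs(fA - fB)), mean(abs(a - b)))
})
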