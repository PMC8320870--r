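test_that("kNN graph modes agree with an exhaustive-distance oracle", {
  pts <- matrix(c(0, 1, 3), ncol = 1)      # collinear points at 0, 1, 3
  gs <- buildKnnGraph(pts, k = 1L, mode = "symmetric")
  expect_equal(edgeSet(gs)[, 1:2, drop = FALSE],
               cbind(lo = c(1L, 2L), hi = c(2L, 3L)), ignore_attr = TRUE)
  gm <- buildKnnGraph(pts, k = 1L, mode = "mutual")
  expect_equal(edgeSet(gm)[, 1:2, drop = FALSE],
               cbind(lo = 1L, hi = 2L), ignore_attr = TRUE)
  # k = N - 1 gives the complete graph in both modes
  set.seed(4)
  cloud <- matrix(rnorm(18), 6, 3)
  for (mode in c("symmetric", "mutual"))
    expect_equal(nrow(buildKnnGraph(cloud, 5L, mode)@edges), choose(6, 2))
  expect_error(buildKnnGraph(cloud, 6L), "k must satisfy")
  expect_error(buildKnnGraph(cloud[0, , drop = FALSE], 1L), "empty")
})

test_that("max-edge bandwidth bounds heat-kernel weights in [exp(-1/2), 1]", {
  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  g <- buildKnnGraph(square, k = 1L, mode = "symmetric")
  expect_equal(computeBandwidth(g), 1)      # unit square 4-cycle
  W <- computeWeights(g, 1)
  expect_equal(unique(round(W@x, 12)), round(exp(-1 / 2), 12))
  # degenerate cloud: sigma^2 = 0 falls back to simple-minded weights
  same <- matrix(1, 5, 2)
  gd <- buildKnnGraph(same, k = 2L)
  expect_equal(computeBandwidth(gd), 0)
  expect_true(all(computeWeights(gd, 0)@x == 1))
  # property: random clouds always satisfy the bound
  for (i in 1:10) {
    set.seed(i)
    cl <- matrix(rnorm(40 * 5), 40, 5)
    gi <- buildKnnGraph(cl, k = 4L)
    wi <- computeWeights(gi, computeBandwidth(gi))@x
    expect_true(all(wi >= exp(-1 / 2) - 1e-12 & wi <= 1 + 1e-12))
  }
})

test_that("Laplacian has zero row sums and component-count zero multiplicity", {
  # single unit edge: L = [[1, -1], [-1, 1]] with eigenvalues {0, 2}
  W1 <- weightsFromEdges(2, cbind(1, 2))
  sys1 <- buildLaplacian(W1)
  expect_equal(as.matrix(sys1@L), matrix(c(1, -1, -1, 1), 2),
               ignore_attr = TRUE)
  expect_equal(eigen(as.matrix(sys1@L))$values, c(2, 0))
  # two disjoint 2-cliques: block-diagonal, two zero eigenvalues
  W2 <- weightsFromEdges(4, cbind(c(1, 3), c(2, 4)))
  expect_warning(sys2 <- buildLaplacian(W2), "connected components")
  expect_identical(sys2@nComponents, 2L)
  ev <- eigen(as.matrix(sys2@L), symmetric = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-12), 2)
  # any W: rows of L sum to zero
  set.seed(9)
  cl <- matrix(rnorm(60), 20, 3)
  g <- buildKnnGraph(cl, 3L)
  sys <- buildLaplacian(computeWeights(g, computeBandwidth(g)))
  expect_lt(max(abs(Matrix::rowSums(sys@L))), 1e-12)
  # asymmetric input rejected
  bad <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3))
  expect_error(buildLaplacian(bad), "symmetric")
})

test_that("complete-graph generalized spectrum matches theory and a dense oracle", {
  # K5 with unit weights: nonzero generalized eigenvalues all n/(n-1)
  n <- 5
  edges <- t(combn(n, 2))
  sys <- buildLaplacian(weightsFromEdges(n, edges))
  emb <- embedManifold(sys, d = n - 1L)
  expect_equal(emb@eigenvalues, rep(n / (n - 1), n - 1), tolerance = 1e-10)
  oracle <- denseGeneralizedEig(sys@L, sys@degree)
  expect_equal(emb@eigenvalues, oracle$values[-1], tolerance = 1e-10)
})

test_that("path-graph embedding matches the dense generalized eigensolver", {
  W <- weightsFromEdges(4, cbind(1:3, 2:4))
  sys <- buildLaplacian(W)
  emb <- embedManifold(sys, d = 1L)
  oracle <- denseGeneralizedEig(sys@L, sys@degree)
  expect_equal(emb@eigenvalues, oracle$values[2], tolerance = 1e-8)
  y <- emb@coords[, 1]
  yo <- oracle$vectors[, 2]
  yo <- yo / sqrt(sum(yo^2 * sys@degree))
  if (sign(yo[1]) != sign(y[1])) yo <- -yo
  expect_equal(y, yo, tolerance = 1e-8)
})

test_that("zero-cluster discarding follows graph connectivity", {
  # three components: two 2-cliques and a triangle
  edges <- rbind(cbind(1, 2), cbind(3, 4), cbind(c(5, 5, 6), c(6, 7, 7)))
  expect_warning(sys <- buildLaplacian(weightsFromEdges(7, edges)))
  expect_identical(sys@nComponents, 3L)
  emb <- embedManifold(sys, d = 2L)
  expect_identical(emb@nDiscarded, 3L)
  expect_true(all(emb@eigenvalues > 1e-8))
  # requesting too many dimensions fails cleanly
  expect_error(embedManifold(sys, d = 5L), "too large")
})

test_that("embedding satisfies the degree-weighted normalization constraints", {
  img <- texturedImage(24, seed = 5)
  cl <- extractPatches(img, 3L)
  g <- buildKnnGraph(cl, k = 6L)
  sys <- buildLaplacian(computeWeights(g, computeBandwidth(g)))
  emb <- embedManifold(sys, d = 3L)
  for (j in 1:3) {
    y <- emb@coords[, j]
    expect_equal(sum(y^2 * sys@degree), 1, tolerance = 1e-8)
    expect_lt(abs(sum(y * sys@degree)), 1e-6)   # y' D 1 ~ 0
  }
  expect_false(is.unsorted(emb@eigenvalues, strictly = TRUE))
  # deterministic under a fixed solver seed
  emb2 <- embedManifold(sys, d = 3L)
  expect_identical(emb@coords, emb2@coords)
})

test_that("sparse eigensolution matches the dense oracle on a real patch graph", {
  img <- texturedImage(20, seed = 3)          # N = 400
  cl <- extractPatches(img, 3L)
  g <- buildKnnGraph(cl, k = 8L)
  sys <- buildLaplacian(computeWeights(g, computeBandwidth(g)))
  emb <- embedManifold(sys, d = 3L)
  oracle <- denseGeneralizedEig(sys@L, sys@degree)
  expect_equal(emb@eigenvalues, oracle$values[2:4], tolerance = 1e-8)
  for (j in 1:3) {
    yo <- oracle$vectors[, 1 + j]
    yo <- yo / sqrt(sum(yo^2 * sys@degree))
    y <- emb@coords[, j]
    if (sum(yo * y) < 0) yo <- -yo
    expect_lt(max(abs(y - yo)), 1e-6)
  }
})

test_that("feature images reshape embedding columns and flag degeneracy", {
  img <- texturedImage(32, seed = 6)
  emb <- imageEmbedding(img, patchSide = 3L, k = 8L, d = 3L)
  f <- featureImages(emb)
  expect_length(f, 3L)
  expect_true(all(vapply(f, function(x) all(dim(x) == c(32L, 32L)),
                         logical(1))))
  expect_true(all(vapply(f, function(x) min(x) == 0 && max(x) == 1,
                         logical(1))))
  expect_error(imageEmbedding(matrix(0.7, 32, 32)), "degenerate")
})

test_that("embeddings round-trip through the columnar text format", {
  img <- texturedImage(16, seed = 14)
  emb <- imageEmbedding(img, k = 6L, d = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEmbedding(emb, path)
  back <- readEmbedding(path)
  expect_equal(back@coords, emb@coords, tolerance = 1e-12)
  expect_equal(back@eigenvalues, emb@eigenvalues, tolerance = 1e-12)
  expect_identical(back@imageDim, emb@imageDim)
  expect_identical(back@nDiscarded, emb@nDiscarded)
})

test_that("the leading feature image separates the regions of a two-region image", {
  # two intensity plateaus with a wavy boundary; noise links the patch
  # clusters into one component while the region cut stays the slowest
  # diffusion mode, so feature 1 is a near-binary region indicator
  n <- 48
  bnd <- n / 2 + 5 * sin(2 * pi * seq_len(n) / n)
  set.seed(8)
  img <- matrix(0.25, n, n)
  for (r in seq_len(n)) img[r, seq_len(n) > bnd[r]] <- 0.75
  img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                           sigma = 0.7))
  img <- img + matrix(rnorm(n * n, sd = 0.03), n)
  emb <- imageEmbedding(rescale01(img), k = 20L, d = 1L)
  f1 <- featureImages(emb)[[1]]
  # compare away from the partial-volume band around the boundary
  a <- unlist(lapply(seq_len(n), function(r) f1[r, 1:floor(bnd[r] - 5)]))
  b <- unlist(lapply(seq_len(n), function(r) f1[r, ceiling(bnd[r] + 5):n]))
  gap <- abs(mean(a) - mean(b))
  expect_gt(gap, 5 * max(sd(a), sd(b)))
})
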