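# Independent oracles and small fixtures, written without reference to the
# package's own implementation paths.

# explicit nested-loop patch gather with replicate-edge padding
bruteForcePatches <- function(image, s) {
  nr <- nrow(image); nc <- ncol(image); h <- (s - 1) / 2
  out <- matrix(0, nr * nc, s * s)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    row <- (r - 1) * nc + c
    k <- 0
    for (dr in -h:h) for (dc in -h:h) {
      k <- k + 1
      rr <- min(max(r + dr, 1), nr)
      cc <- min(max(c + dc, 1), nc)
      out[row, k] <- image[rr, cc]
    }
  }
  out
}

# dense generalized eigensolver for L y = lambda D y via the symmetric
# reduction D^-1/2 L D^-1/2 (base eigen; independent of the sparse path)
denseGeneralizedEig <- function(L, deg) {
  L <- as.matrix(L)
  s <- 1 / sqrt(deg)
  C <- t(L * s) * s          # D^-1/2 L D^-1/2
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  o <- order(e$values)
  list(values = e$values[o],
       vectors = sweep(e$vectors[, o, drop = FALSE], 1, s, `*`))
}

# naive double-loop mean squared error
naiveMse <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    acc <- acc + (a[i, j] - b[i, j])^2
  acc / length(a)
}

# mutual information from an explicitly assembled joint table
naiveMI <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  acc <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) acc <- acc + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  acc
}

# weight matrix assembled directly from an edge list
weightsFromEdges <- function(n, edges, w = rep(1, nrow(edges))) {
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                       j = c(edges[, 2], edges[, 1]),
                       x = c(w, w), dims = c(n, n))
}

# small deterministic textured image (smooth blob + seeded texture)
texturedImage <- function(n = 64, seed = 1) {
  withr::with_seed(seed, {
    g <- outer(seq(-1, 1, length.out = n), seq(-1, 1, length.out = n),
               function(a, b) exp(-3 * (a^2 + 1.4 * b^2)))
    rescale01(g + 0.15 * matrix(stats::rnorm(n * n), n))
  })
}

# sorted edge list of a NeighborGraph, for comparison with expectations
edgeSet <- function(graph) {
  e <- graph@edges
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}
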