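setMethod("show", "PatchCloud", function(object) {
  cat("PatchCloud:", nrow(object@points), "points in",
      ncol(object@points), "dimensions (patch",
      paste0(object@patchSide, "x", object@patchSide), "over",
      paste(object@imageDim, collapse = " x "), "image)\n")
})

setMethod("show", "NeighborGraph", function(object) {
  cat(object@mode, "kNN graph: ", object@nNodes, " nodes, ",
      nrow(object@edges), " edges (k = ", object@k, ")\n", sep = "")
})

setMethod("show", "LaplacianSystem", function(object) {
  cat("LaplacianSystem: ", nrow(object@L), " x ", ncol(object@L),
      " sparse, ", object@nComponents, " connected component(s)",
      if (!is.na(object@sigmaSq)) paste0(", sigma^2 = ",
                                         signif(object@sigmaSq, 4)),
      "\n", sep = "")
})

setMethod("show", "ManifoldEmbedding", function(object) {
  cat("ManifoldEmbedding: ", nrow(object@coords), " points in ",
      ncol(object@coords), " dimensions (", object@nDiscarded,
      " zero-cluster vector(s) discarded)\n  eigenvalues: ",
      paste(signif(object@eigenvalues, 4), collapse = ", "), "\n", sep = "")
})

setMethod("show", "PrincipalFrame", function(object) {
  cat("PrincipalFrame in", length(object@centroid), "dimensions\n",
      " variances:", paste(signif(object@variances, 4), collapse = ", "),
      "\n")
})

setMethod("show", "ManifoldAlignment", function(object) {
  cat("ManifoldAlignment: sign flips (",
      paste(object@signFlips, collapse = ", "), "), rotation det ",
      signif(det(object@rotation), 6), "\n", sep = "")
})

setMethod("show", "SimilarityTransform2D", function(object) {
  cat(if (object@scale == 1) "Rigid" else "Similarity",
      " transform: theta = ", signif(object@theta, 6), " rad (",
      signif(object@theta * 180 / pi, 4), " deg), t = (",
      signif(object@tx, 6), ", ", signif(object@ty, 6), ") px, scale = ",
      signif(object@scale, 6), ", center = (",
      paste(signif(object@center, 6), collapse = ", "), ")\n", sep = "")
})

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult [", object@method, "]: ",
      if (object@converged) "converged" else "NOT converged", " in ",
      object@iterations, " iterations, metric = ",
      signif(object@metric, 6), "\n", sep = "")
  show(object@transform)
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom: ", paste(dim(object@image), collapse = " x "), ", ",
      max(object@labels), " structure(s), ", nrow(object@landmarks),
      " landmarks\n", sep = "")
})

setMethod("show", "ModalityMap", function(object) {
  cat("ModalityMap '", object@name, "': levels ",
      paste(signif(object@levels, 3), collapse = ", "), "; noise ",
      object@noiseSigma, ", bias ", object@biasAmplitude, "\n", sep = "")
})

setMethod("show", "PhantomPair", function(object) {
  cat("PhantomPair (seed ", object@seed, "): ",
      paste(dim(object@reference), collapse = " x "), ", overlap ",
      signif(object@overlapFraction, 3), "\n  true aligning ", sep = "")
  show(object@trueTransform)
})
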