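# ManifoldReg

Rigid and similarity registration of **multi-modal** 2-D medical images
(CT vs. MR, T1 vs. T2, ...) by first transforming both images into a
shared **mono-modal** intensity coordinate system, for researchers and
engineers who need cross-modality alignment with full *or only partial*
overlap between the two fields of view.

Different modalities draw the same anatomy with unrelated intensity
scales, so mono-modal similarity metrics (MSE, phase correlation) fail
across modalities, and the usual alternative, mutual information,
degrades when the images overlap only partially.  ManifoldReg instead
computes a modality-insensitive *structural representation* of each
image and registers those:

1. **Patch manifold** — every pixel of an *n*<sub>r</sub> ×
   *n*<sub>c</sub> image contributes its vectorized *s* × *s* patch
   (default 3 × 3), giving *N* = *n*<sub>r</sub>*n*<sub>c</sub> points
   in *D* = *s*² dimensions.
2. **Laplacian eigenmap** — a symmetric *k*-nearest-neighbour graph
   (default *k* = 10) with heat-kernel weights
   *w*<sub>ij</sub> = exp(−‖x<sub>i</sub> − x<sub>j</sub>‖² / 2σ²),
   σ² set to the maximum squared edge length (bounding all weights in
   [e<sup>−1/2</sup>, 1]), is built on the patch cloud; the *d* (= 3)
   generalized eigenvectors of *L* y = λ *D* y above the zero cluster,
   reshaped to image geometry, are the **feature images**.
3. **Manifold alignment** — per-eigenvector sign (reflection) ambiguity
   is fixed by the sign of the covariance between corresponding feature
   images; the sensed embedding is then rigidly mapped onto the
   reference embedding through their principal frames
   (R = B Aᵀ, p′ = R(p − c<sub>s</sub>) + c<sub>r</sub>).
4. **Mono-modal registration** — MSE rigid registration with a
   regular-step gradient-descent optimizer and multiresolution pyramid
   for fully overlapping images; Fourier–Mellin log-polar phase
   correlation (translation + rotation + scale) for partially
   overlapping ones.  Histogram mutual information (50 bins) and
   landmark mean absolute error evaluate the result.

A synthetic generator (`makePhantom`, `modalityMap`, `makePair`)
produces brain-phantom-like multi-modal pairs with known ground-truth
transforms, landmarks and partial-overlap crops, so the whole pipeline
is testable without any data download.

## Worked example

```r
library(ManifoldReg)

ph   <- makePhantom(c(200, 200), nStructures = 3, seed = 11)
pair <- makePair(ph, modalityMap("t1"), modalityMap("t2"), seed = 11)
pair
#> PhantomPair (seed 11): 200 x 200, overlap 1
#>   true aligning Rigid transform: theta = -0.330374 rad (-18.93 deg),
#>   t = (8.27809, 0.661348) px, scale = 1, center = (99.5, 99.5)

res <- registerMultimodal(pair@reference, pair@sensed)
res
#> RegistrationResult [pipeline]: converged in 156 iterations, metric = 0.0121537
#> Rigid transform: theta = -0.322318 rad (-18.47 deg),
#> t = (8.35428, 0.543935) px, scale = 1, center = (99.5, 99.5)

landmarkMAE(pair@trueTransform, res@transform, pair@landmarks)
#> [1] 0.5267094

reg <- res@details$registered
mutualInformation(pair@reference, pair@sensed)                      # before
#> [1] 0.6666477
mutualInformation(pair@reference, reg, mask = validMask(reg))       # after
#> [1] 0.9615862
```

The sensed T2-like image, drawn with an inverted intensity scale and
warped by an unknown rigid transform, is aligned to within about half a
pixel of the truth (landmark mean absolute error 0.53 px), and the
mutual information between the original modality pair rises from 0.67
to 0.96 nats — even though MI was never optimized, only MSE on the
feature images.

For partially overlapping images use
`registerMultimodal(ref, sen, multimodalControl(mode = "partial"))`,
which hands the aligned feature images to the Fourier–Mellin backend
(`registerFMT`).  Lower-level entry points (`extractPatches`,
`buildKnnGraph`, `embedManifold`, `featureImages`, `alignEmbeddings`,
`registerRigid`, ...) expose every stage; `inst/cli/manifoldreg.R` is a
thin command-line front end with `transform`, `register`, `simulate`
and `evaluate` subcommands.

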