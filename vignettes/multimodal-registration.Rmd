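---
title: "Multi-modal image registration through Laplacian eigenmap structural representations"
author: "ManifoldReg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal image registration through Laplacian eigenmap structural representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Registering a CT slice to an MR slice, or a T1- to a T2-weighted MR
image, is hard precisely because the two modalities draw the same
anatomy with unrelated intensity scales: cerebrospinal fluid is dark in
T1 and bright in T2, bone is bright in CT and void in MR.
Intensity-based similarity metrics built for mono-modal data (mean
squared error, cross-correlation, phase correlation) are meaningless
across modalities, and the usual escape route, mutual information,
struggles when the two images overlap only partially, because the joint
histogram is then dominated by unmatched content.

ManifoldReg implements a *multi-modal to mono-modal transformation*:
both images are re-expressed as modality-insensitive "feature images"
that depict internal structure rather than acquisition-specific
intensity, after which plain mono-modal machinery — mean-squared-error
rigid registration for fully overlapping images, Fourier–Mellin
log-polar phase correlation for partially overlapping ones — applies
directly.

## The transformation

**Patch manifold.** Every pixel of an $n_r \times n_c$ image (rescaled
to $[0,1]$) contributes the vectorized $s \times s$ patch centered on
it, giving $N = n_r n_c$ points in $D = s^2$ dimensions; borders are
completed by replicate-edge padding, and rows follow raster order so
that embedding vectors reshape back to image geometry.  Small patches
preserve detail; large ones blur it.  The default is $s = 3$
($D = 9$), so a $200 \times 200$ image becomes a
$40{,}000 \times 9$ matrix.

**Graph.** A symmetric $k$-nearest-neighbour graph (edge if *either*
endpoint lists the other; $k = 10$ by default, $k = 20$ as a
conservative preset for noisy inputs) connects the patch points.  The
symmetric rule, unlike the mutual one, tends toward a single connected
component.  Edge weights are heat-kernel values
$w_{ij} = \exp(-\|x_i - x_j\|^2 / 2\sigma^2)$ with the bandwidth set by
the *max-edge rule* $\sigma^2 = \max_{(i,j) \in E} \|x_i - x_j\|^2$,
which bounds every weight between $e^{-1/2} \approx 0.606$ and 1 and
needs no tuning scan.  (The bound holds only under the edge-wise
maximum; a maximum over all point pairs would push weights of long
edges above the bound's premise, which is why the edge-wise reading is
the default and a fixed `sigmaSq` can be supplied where the user wants
anything else.)  If every connected pair coincides ($\sigma^2 = 0$) the
simple-minded scheme $w_{ij} = 1$ is used.

**Spectral embedding.** With degrees $d_{ii} = \sum_j w_{ij}$ and
Laplacian $L = D - W$, the embedding solves the generalized problem
$L y = \lambda D y$ and keeps the $d$ eigenvectors above the zero
cluster, whose multiplicity equals the number of connected components —
counted from graph connectivity (union–find), never by thresholding
eigenvalues, because iterative solvers return near-zeros rather than
zeros.  A disconnected graph is accepted with a warning recommending a
larger $k$ or pre-smoothing.  Each retained eigenvector is scaled to
$y^\top D y = 1$ and given a canonical sign (first non-negligible entry
positive) so repeated runs are bit-identical; columns reshaped to image
geometry and min–max rescaled are the feature images.  The default
embedding dimension is $d = 3$.

**Solver.** The pencil is reduced to the normalized adjacency
$D^{-1/2} W D^{-1/2}$, whose *largest* eigenpairs correspond one-to-one
to the smallest generalized eigenpairs.  Those extremal pairs are found
by implicitly restarted Lanczos iteration with a seeded start vector —
matrix–vector products only, no factorization.  We profiled the
alternative, shift-invert with a sparse Cholesky factorization, at
$N = 40{,}000$: the factorization costs roughly ten seconds per image
against about one second for the matvec-only route, with eigenvalues
agreeing to $10^{-10}$; the factorized route remains as an automatic
fallback when Lanczos does not converge, and tiny systems
($N \le 64$) are solved densely.  Solver tolerance (`1e-9`) and
iteration cap are configuration knobs, as the appropriate values are
data-dependent.

## Alignment of the two embeddings

Eigenvectors are defined only up to sign, and two independently
computed embeddings may also disagree by a rigid motion in embedding
space.  Alignment proceeds in two steps:

1. **Sign correction.** Axes are paired by eigenvalue rank and, for
   each pair, the covariance between the reference and sensed
   coordinates over raster-aligned pixels is computed; a negative
   association means the sensed axis is reflected, and it is negated.
   This presumes the images roughly share framing — under severe
   initial misalignment or heavy cropping the covariance shrinks toward
   noise (we measure values near $10^{-7}$ on 50 %-overlap pairs), a
   documented limitation inherited by design.

2. **Principal-frame rotation.** PCA frames of both clouds give
   $R = B A^\top$ mapping the sensed directions $A$ onto the reference
   directions $B$, and points move as $p' = R(p - c_s) + c_r$.  PCA's
   own sign ambiguity is removed by making each direction's
   largest-magnitude entry positive; if $\det R = -1$ the
   lowest-variance sensed direction is flipped so $R$ stays a proper
   rotation; tied variances order stably by axis index.

A numerical subtlety matters here: because each eigenvector is
normalized to $y^\top D y = 1$, the embedded cloud is close to
isotropic — its principal variances typically agree within a few
percent.  Eigenvectors of a nearly degenerate covariance are arbitrary
within the tied subspace, and two independently computed frames then
disagree by a *random* rotation, which would scramble the feature
images.  `alignEmbeddings` therefore replaces the eigenbasis of any
group of variances tied within `tieTol` (default 5 %) by the
axis-aligned orthonormal basis of the same subspace, computed from the
group's projector.  Well-separated variances keep their exact principal
directions, so the behaviour on anisotropic clouds is unchanged (the
unit tests recover a constructed 3-D rotation to $10^{-6}$), while on
degenerate clouds the rotation degrades gracefully to the identity and
alignment reduces to sign correction plus a centroid shift.

## Registration backends

**Full overlap — MSE rigid.** The chosen pair of feature images is
registered by minimizing the masked mean squared error over rotation
and translation about the image center, with a regular-step gradient
descent: a fixed-length step along the negative normalized
central-difference gradient, the length multiplied by a relaxation
factor (0.5) on every gradient direction reversal, on a stalled step
(relative improvement below `metricTol`), and on a rejected (worse)
step, terminating below a minimum step.  The angle is handled in
degrees so one optimizer unit moves the periphery by roughly one pixel,
matching the translations' pixel units.  None of these hyperparameters
appear in the original account of the method; the defaults (initial
step 2, minimum $10^{-4}$, 300 iterations per level) follow common
regular-step implementations and are exposed in
`rigidRegControl`.  A three-level multiresolution pyramid extends the
capture range to the $\pm\pi/4$ rotations used in the evaluation
protocol, and the coarsest level is initialized by a rotation grid
(every 6°) whose candidate angles each receive their own translation
from a coarse phase correlation — the cheap-level MSE landscape over
rotation alone is deceptive at a fixed translation — with descent
multi-started from the best three poses.

**Partial overlap — Fourier–Mellin.** The classic chain: apodize on a
common power-of-two square, take fftshifted FFT magnitudes with the
Reddy–Chatterji high-pass emphasis, resample onto a log-polar grid,
phase-correlate there to read rotation (modulo 180°) and scale, then
de-rotate/de-scale and phase-correlate again for translation, with
parabolic sub-bin peak interpolation throughout.  Feature images,
however, are smooth and piecewise constant: their spectral energy sits
near DC, crop edges dominate the high frequencies, and the textbook
chain locks onto axis-aligned artifacts.  `fmtControl`'s defaults are
therefore tuned for feature images: a 1 % percentile clip (removing
localized eigenvector spikes that would otherwise consume the min–max
range), correlation of gradient-magnitude images (restoring broadband
content; the gradient magnitude is translation-, rotation- and, up to a
constant, scale-covariant), log-compressed magnitudes, a radial Hann
window on the log-polar maps, and — instead of trusting the single
global correlation argmax — the strongest `topK` (5) local maxima, each
with its 180° twin, *verified* by the translation-stage correlation
peak, which is sharply discriminative at the true pose.
`classicFmtControl()` restores the textbook chain; it is the
appropriate baseline for what plain Fourier–Mellin registration
achieves without the mono-modal transformation, and it recovers
mono-modal similarity transforms (including 40 % crops) to sub-pixel,
sub-degree accuracy.

One caveat the package states openly: gradient magnitudes are invariant
to a *global* intensity inversion, so the gradient-enhanced chain can
incidentally register raw image pairs whose modalities are related by
an approximate global inversion — as this package's own synthetic
presets are.  Real modality pairs differ boundary by boundary, not by a
single monotone map; conclusions about raw-image baselines should be
drawn from the classic chain.

**Pipeline.** `registerMultimodal` runs: embedding of each image
independently → sign correction and alignment → backend on a feature
pair → the estimated transform applied to the original sensed image.
Eigenvalue crossings between the two manifolds can permute feature
rank (modality differences perturb the spectrum), so by default the
backend channel is chosen by the strongest absolute pixel correlation
among feature pairs — with a flip when the best match is
anti-correlated — in full-overlap mode, and by the verification peak
over all feature pairs in partial mode (`featureScan = FALSE` restores
strict rank pairing on feature 1).  Alignment itself always uses rank
pairing; the scan is a backend selection step.

## The synthetic study system

No imaging data ships with the package; a generator emulates the
structure the method relies on — different modalities of one anatomy
share internal structure:

* `makePhantom` draws a background plus nested, harmonically perturbed
  elliptical "tissues" ($r(\varphi) = r_0 \prod_m (1 + a_m \cos(m
  \varphi + \psi_m))$, $|a_m| \le 0.08$, slightly offset centers) with
  distinct labels and five landmarks inside the object, all
  deterministic per seed.
* `modalityMap` presets assign per-tissue intensities.  The "t1"-like
  preset brightens tissue from 0.25 to 0.9 over a dark surround; the
  "t2"-like preset inverts the *whole* scale, bright surround included.
  That full inversion is a deliberate idealization: with dark surrounds
  in both presets (as in real MR) the background — roughly half the
  frame — makes the raw Pearson correlation strongly positive no matter
  how the tissues are ordered, whereas the study system is designed so
  that raw-intensity similarity is genuinely misleading (correlation
  about $-0.95$) while the underlying structure is shared.
* `simulateModality` adds a smooth nonlinearity, a 0.8 px Gaussian
  partial-volume blur, a seeded low-frequency multiplicative bias field
  (amplitude 0.20) and Gaussian noise (sd 0.03), echoing the 3 % noise
  / 20 % non-uniformity settings customary for simulated brain MR.
* `makePair` warps the second modality by a similarity transform with
  rotation uniform in $[-\pi/4, \pi/4]$, translations
  rejection-sampled so the object stays fully in frame, optional scale
  (the partial-overlap experiments use $[0.8, 1.5]$, within the less
  than 2× range Fourier–Mellin can recover), and, for partial overlap,
  crops the sensed frame from a seeded side until only the requested
  fraction of the warped object remains, filling the removed field with
  the modality's background level.  The stored ground truth is the
  aligning transform (the inverse of the applied warp).

What the phantom does *not* emulate: anatomical detail and asymmetry
(real brains produce richer, better-separated Laplacian spectra — the
tied-variance degeneracy above is *harsher* here than on real data),
modality-specific artifacts (bone shadowing, susceptibility), partial
modality-specific structure (a boundary visible in only one modality),
and 3-D geometry.  Passing tests therefore demonstrate the machinery
end to end under controlled ground truth, not clinical performance.

## Problem sizes in the test suite

The package's experiment-scale tests use $200 \times 200$ images
(40,000-node graphs): 30 seeded full-overlap pairs for the rigid
protocol (median landmark error below 2 px; mutual information, 50
bins, must increase after registration in at least 90 % of converged
runs) and 10 seeded partial pairs at 50–70 % overlap with scale in
$[0.8, 1.5]$ (feature-image Fourier–Mellin within 3 px in at least
8/10, classic raw Fourier–Mellin failing in at least 8/10).  Unit
tests run on $16$–$96$ px images, where the dense generalized
eigensolver serves as the oracle for the sparse path.

## Known limitations

* 2-D slices only; the graph and eigenproblem sizes grow quadratically
  with volume side, which is why 3-D is out of reach for this
  formulation.
* The sign-correction covariance weakens under severe initial
  misalignment and heavy cropping; the partial-overlap path compensates
  through the spectrum-based (sign-insensitive) rotation/scale stage
  and verification scan, the full-overlap path through the correlation
  flip in channel selection.
* Mutual information values are reported in nats over 50 per-image
  min–max bins; no comparability to any externally published absolute
  MI values is claimed.
* Structures must be visible in both modalities — the transformation
  represents shared structure and cannot invent correspondence that is
  not there.
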