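---
title: "Spectrogram surfaces and distortion signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrogram surfaces and distortion signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectromesh)
```

## The model

`spectromesh` turns a one-dimensional audio signal into a geometric object
and measures that object's shape. The pipeline has four stages.

**1. Surface.** The magnitude spectrogram of the signal is treated as the
graph surface \(S = \{(x, y, z(x, y))\}\) with \(x\) time, \(y\) frequency
and \(z\) the log-magnitude. The surface is sampled on a uniform
\(N \times N\) grid and each axis is affinely normalized to \([0, 1]\),
with \(z\) additionally multiplied by an aspect factor \(\alpha\). The
normalization matters: distortion values are meaningless without a declared
unit convention, so the original spans and the transform are kept in
`scale_meta`.

**2. Mesh.** The grid is lifted to vertices \((x_i, y_j, z_{ij})\) and
triangulated in the \((x, y)\) plane. On a uniform grid the Delaunay
triangulation is tie-degenerate (all four cell corners are co-circular), so
the tie is broken deterministically toward the "/" diagonal; the result is
reproducible across platforms and has exactly \(2(N-1)^2\) counterclockwise
triangles. Connectivity depends only on the planar grid — heights never
change it — and a graph surface over a grid is automatically a manifold
disk, which is what planar flattening requires.

**3. Flattening.** A piecewise-affine map \(f\) of the mesh into the plane
is computed by solving
\[
  f^* = \arg\min_f E(f) \quad \text{s.t.} \quad \det df_t > 0 \;\;
  \forall t,
\]
with \(E\) the (area-weighted) symmetric Dirichlet energy,
\(\tfrac14(\sigma_1^2 + \sigma_1^{-2} + \sigma_2^2 + \sigma_2^{-2})\) of
the per-triangle Jacobian singular values. The orientation constraints make
the map locally injective. The solver is a two-step scheme:

* *Tutte initialization*: the boundary loop is placed on the unit circle,
  spaced proportionally to the 3D boundary edge lengths, and interior
  vertices solve the convex-combination (mean-value weights) sparse linear
  system. On a disk mesh with a convex boundary this map is bijective, so
  the descent never has to repair inverted triangles.
* *Flip-free descent*: monotone line-search descent of the barrier energy.
  The descent direction solves against the source mesh's cotangent
  Laplacian (a Sobolev-type preconditioner — the exact Hessian of the
  Dirichlet part of the energy), and every step is capped at 0.9 times the
  smallest step at which any triangle determinant would reach zero along
  the direction (the smallest positive root of a per-triangle quadratic).
  Together with the barrier property of the energy this guarantees
  \(\det df_t > 0\) at every accepted iterate, which the energy trace
  records and the tests check exhaustively.

A design note on the preconditioner: a plain diagonal preconditioner also
converges, but orders of magnitude more slowly; it cannot reach the
\(10^{-6}\)-level singular-value accuracy on flat surfaces that the
flat-limit contract demands within a practical iteration budget. The
cotangent-Laplacian solve (factored once, reused every iteration) achieves
it in a few hundred iterations. `flatten_config(preconditioner =
"diagonal")` keeps the simpler variant available.

The boundary is free during minimization: pinning it to the initial disk
would force large isometric distortion that reflects the arbitrary target
shape rather than the surface's own geometry. Free-boundary minimization
requires a barrier energy (symmetric Dirichlet or MIPS here); a bounded
energy could drive triangles to collapse through the boundary.

**4. Signature.** For each triangle the Jacobian is expressed in a
right-handed orthonormal frame erected in the triangle's own plane, so its
signed singular values \(\sigma_1 \ge |\sigma_2|\) are invariant to rigid
motions of the source surface. Eight closed-form energies score the local
deformation: ARAP and symmetric Dirichlet and quasi-isometric dilatation
(length), quasi-conformal dilatation and MIPS (angle), unsigned area
distortion (area), Dirichlet energy and conformal factor (scale). Triangles
are split at the median of their centroid frequencies — strictly below the
median into the low band, at-or-above into the high band — and each energy
is aggregated per band by area weighting,
\[
  D_{\Im_0}(f, E) =
  \frac{\sum_{t \in \Im_0} E(\sigma_1, \sigma_2)\,\mathrm{area}(t)}
       {\sum_{t \in \Im_0} \mathrm{area}(t)},
\]
giving \(8 \times 2 = 16\) features per recording. The weights use the
*source* (3D) triangle areas so they describe the signal's own geometry,
not the map being scored; whether source or image areas were intended is
not decidable from the printed definition, and the source choice makes the
features of one surface directly comparable across candidate maps. All
eight energies are evaluated on the single length-minimizing flattening
rather than on eight separately optimized maps: the signature is defined as
the distortions *of the flattening*, and one map keeps the cost at one
optimization per recording.

Degenerate inputs are kept well-defined: a constant-frequency mesh has an
empty low band, in which case the low-band features fall back to the
full-mesh global distortions with a warning, so the signature is always a
16-vector.

## Preprocessing

Two denoising front ends mirror the two application families:

* **Savitzky–Golay** (`savitzky_golay`) for stethoscope-type signals:
  each sample is replaced by the centre value of the degree-\(N\)
  least-squares polynomial over its \(2M{+}1\)-sample window (defaults
  \(N = 3\), \(M = 11\)). Polynomials of degree \(\le N\) pass through
  unchanged — the tests assert this to \(10^{-9}\). At the first and last
  \(M\) samples the polynomial is fitted on the truncated one-sided window,
  preserving the signal length; the filter's published form is silent on
  edges and this is the standard choice. The textbook window polynomial is
  written without a constant term in some sources; a constant signal can
  only be reproduced with the intercept included, so the intercept is
  included.
* **MODWT thresholding** (`modwt_denoise`) for speech-type signals: the
  maximal-overlap (undecimated) wavelet transform with Haar or Daubechies-4
  filters, soft (or hard) thresholding at the universal threshold
  \(\hat\sigma\sqrt{2\log n}\) with \(\hat\sigma\) the MAD estimate from
  the level-1 details, and exact inversion. The transform is
  perfect-reconstruction: a zero threshold returns the input to round-off.

## Spectrogram parameters

The analysis window defaults to the power of two giving roughly four STFT
frequency bins per target grid row (e.g. 256 samples for the default
`grid_N = 32`), with 75% overlap, shrunk when the recording is too short
to fill `grid_N` frames. Resampling onto the grid is box-averaged per axis
whenever the grid is coarser than the spectrogram: each grid sample is the
mean of the source samples in its cell. This anti-aliasing is load-bearing.
A clean tone's spectral ridge can be far narrower than a grid cell; point
interpolation would make the surface — and every downstream feature —
depend on the accidental alignment of the ridge with the grid rows, which
in experiments inflated within-class feature variance by an order of
magnitude. The mel variant (64 bands by default, HTK mel scale) is
available for speech-type signals via `kind = "mel"`.

`grid_N` defaults to 64 for standalone surface export and 32 in the
corpus-level feature extraction used by the examples and tests (4,096 vs
1,024 vertices); 32 keeps a full 120-recording experiment within about a
minute while leaving the signature's class structure intact. The z aspect
\(\alpha\) defaults to 1 (the surface box is a unit cube).

## Classification protocol

The MFCC baseline extracts 12 cepstral coefficients per frame (log mel
energies, orthonormal DCT-II, dropping the 0th coefficient) and summarizes
each trajectory with six statistics — mean, standard deviation, min, max,
mean and standard deviation of the absolute successive differences — for
72 features. The combined model joins both tables (88 features) and keeps
the 45 most important by random-forest ranking fitted on the training rows
only; fitting the selector inside the training side avoids a leakage the
protocol would otherwise silently admit.

Evaluation always splits at the *group* (patient / speaker) level,
stratified by class, 80/20 by default: no subject ever contributes to both
sides. Hyper-parameters are drawn from documented random grids and chosen
by fivefold grouped cross-validation on the training side — the objective
is accuracy for multiclass tasks and AUROC for binary ones — with class
weights inverse to the training class frequencies. Reported metrics are
accuracy, recall and the Jaccard-style score
\((TP + TN) / (2(P + N) - (TP + TN))\), macro-averaged one-vs-rest for
multiclass tasks (the averaging convention is the package's choice; the
printed definitions are binary), plus AUROC (one-vs-rest macro for
multiclass). k-NN has no native class weighting; its vote shares are used
as probabilities. Feature rankings come from random-forest permutation
importance or, alternatively, Monte-Carlo Shapley sampling over the fitted
forest's probabilities.

## What the synthetic generator does and does not show

`generate_signals()` builds seeded corpora of amplitude-modulated (possibly
chirped) carriers plus band-limited and white noise at stated SNRs, with
round-robin group labels so grouped splitting is always exercised. The
stock scenarios are illustrative: `lung_like_spec()` (tonal "wheeze" /
broadband "crackle" / noisy "healthy" surrogates), `speech_like_spec()`
(formant-band chirps), and `tonal_vs_broadband_spec()`, the two-class
geometric benchmark used in the end-to-end tests.

The benchmark's two classes differ in *surface texture*: a clean AM tone
yields a smooth spectrogram surface that is nearly developable (its
symmetric Dirichlet distortion is close to the flat-limit value 1), while
noisy broadband activity yields a rough, strongly curved surface. That is
the kind of difference the distortion signature measures directly. A
finding from building this fixture is worth recording: classes that differ
only in *where* a single smooth ridge sits in frequency are barely
separable by flattening distortion — a smooth ridge is near-developable
wherever it sits — even though they are trivially separable by band energy.
Passing the end-to-end test therefore shows the pipeline discriminates
geometric texture under the grouped protocol; it does not show that
distortion features subsume spectral-location features on real data, and on
real corpora the combined distortion + MFCC model is the intended
configuration.

Synthetic recordings are stationary mixtures with independent noise; real
lung sounds and speech have transients, nonstationary envelopes, recording
artifacts and subject-level acoustic correlations the generator does not
model (group labels are assigned, not acoustically induced). Results on the
synthetic benchmark are a correctness check of the machinery, not an
estimate of clinical or phonetic performance.

## Numerical choices and edge cases

* Descent stops on a gradient max-norm below `grad_tolerance` (1e-8), a
  stalled line search (no representable energy decrease), or `max_iters`
  (2000 by default; the heavy test loops cap it explicitly since
  injectivity and monotonicity hold at every iterate regardless).
  The relative-decrease stop is disabled by default because descent crosses
  near-flat plateaus long before convergence.
* The flip cap solves \(\det(J_t + \alpha\,dJ_t) = 0\) per triangle in
  closed form; linear (degenerate-quadratic) cases are handled explicitly.
* The Tutte system is solved with a sparse Cholesky factorization; the
  cotangent Laplacian gets a relative \(10^{-8}\) diagonal shift to absorb
  the free-boundary translation null space.
* Jacobian signed SVDs use the closed 2x2 form
  (\(\sigma_{1,2} = Q \pm R\) with \(Q, R\) the norms of the
  conformal/anti-conformal parts), so \(\sigma_2\) carries the orientation
  sign exactly; an independent `svd()`-based oracle checks this to
  \(10^{-10}\).
* Median band split: strictly below the median goes to band 1, ties go up;
  with an even triangle count the median is the midpoint of the two middle
  centroid frequencies. These conventions are asserted on even, odd, tied
  and constant cases.
* Magnitude transform: \(\log_{10}(\text{mag} + 10^{-10})\); silence maps
  to a constant (hence exactly flat) surface.
* Savitzky-Golay near the ends reduces the fitted degree if a truncated
  window has fewer than \(N + 1\) samples.

## Known limitations

* The distortion minimization is non-convex; the solver returns a local
  minimum reachable from the Tutte initialization. Different
  initializations can give different signatures, which is why the
  configuration (and its hash in the signature provenance) pins the scheme.
* Only disk-topology meshes are supported — exactly what grid graph
  surfaces provide. There is no repair path for non-injective
  initializations; the solver rejects them.
* Phase information, complex spectrograms, reassignment, curvature-adaptive
  sampling and volumetric (tetrahedral) extensions are out of scope.
* Recordings are summarized by one feature vector each; long recordings
  are not chunked into segments.
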