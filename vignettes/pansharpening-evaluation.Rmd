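---
title: "Pansharpening algorithms, quality indices and rank aggregation in fuseval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pansharpening algorithms, quality indices and rank aggregation in fuseval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseval)
```

## The problem

A very-high-resolution satellite such as WorldView-2 delivers eight
multispectral (MS) bands at 1.84 m and one panchromatic (PAN) band at
0.46 m whose 450–800 nm span covers only MS bands 2–6. Pansharpening
estimates the MS bands at the PAN grid by injecting the PAN's spatial
detail into the upsampled MS. No single algorithm is best everywhere: the
injected detail helps or harms depending on how the scene's spatial and
spectral structure interact, so practitioners compare several algorithms
with several quality indices and aggregate the outcome into a ranking.
`fuseval` implements that comparison pipeline end to end, together with a
synthetic scene generator that stands in for commercial imagery.

Throughout, images are non-negative double-precision arrays; the MS grid
convention is block-centred: coarse pixel $(i,j)$ (0-based) owns the fine
block $[ri, ri+r) \times [rj, rj+r)$, and all resampling, boundary
handling (half-sample reflection) and block statistics follow it. Images
are assumed co-registered; no registration is attempted.

## Fusion algorithms

All four fusers take the MS image already interpolated to the PAN grid
(`upsample_ms()`, bicubic Catmull–Rom by default) and return a fused
image on that grid. Negative outputs are clipped to zero; there is no
upper clip.

**FIHS.** The intensity $I$ is the unweighted mean of the injected bands
(all eight by default; `inject_bands` selects a subset). The PAN plane is
moment-matched to $I$ (mean and standard deviation made equal) and the
same detail plane $PAN_m - I$ is added to every injected band. The
moment matching is a choice, not part of the method's classical
statement: without it, any radiometric offset between the PAN and the
intensity appears as a gross bias in every band. A `pan_match = "none"`
switch exposes the raw form.

**HCS.** Each pixel's band vector is viewed in hyperspherical
coordinates; the radius $\sqrt{\sum_i MS_i^2}$ is replaced by a
moment-matched PAN value while the angles are untouched, which rescales
the whole vector and therefore preserves every band ratio (the spectral
angle between input and output is zero up to rounding). This is the
direct-substitution ("naive") form; smoothed variants found in the
literature are intentionally out of scope.

**MTF_GLP_HPM.** A low-resolution PAN is synthesised per band by
filtering with a Gaussian whose frequency response at the Nyquist of the
4×-reduced grid equals the band's sensor MTF gain (default 0.35 for
every band — a nominal literature value, overridable per band), then
block-averaging down by the ratio and re-expanding bicubically — one
generalized-Laplacian-pyramid stage with scale factor 4. High-pass
modulation multiplies each band by $PAN / PAN_{low}$. Division is
guarded: where $PAN_{low} < 10^{-6} \cdot \overline{PAN}$ the MS value
passes through unchanged. The Gaussian's width is solved numerically on
the *discrete* kernel response (bisection via `uniroot` to $10^{-12}$),
because the continuous-domain formula misses the target gain by several
percent for narrow kernels; the package meets the requested Nyquist gain
to well under $10^{-3}$.

**WAT⊗FRAC.** The PAN is moment-matched to each band, decomposed with
the undecimated *à trous* transform (separable B3-spline kernel
$[1,4,6,4,1]/16$; $\log_2 r$ levels, i.e. two for ratio 4 — the residual
plus detail planes reconstruct the input to machine precision), and the
summed detail planes are injected with a per-pixel weight
$\alpha_i(x,y)$. The weight is the band's fractal dimension map:
differential box counting over a sliding $w \times w$ window
(implemented in C++; edges handled by reflection), with the raw
dimension clamped to $[2,3]$ and rescaled linearly to $[0,1]$. Flat
surfaces (dimension 2) receive no detail, highly textured ones receive
it fully — this is what lets the method leave homogeneous areas smooth.
One $\alpha$ map per band weights all wavelet levels identically; the
alternative of per-level weights was considered and rejected as
under-determined (nothing in the method's description distinguishes the
levels). Window sizes 7, 15 and 27 are the standard choices — small
windows for heterogeneous scenes (shrubland: 7), large for smooth ones
(coastal: 27), intermediate for mixed scenes (15); other odd sizes ≥ 7
are accepted with a warning. The `alpha` argument can override the maps
entirely: `alpha = 0` is the identity, `alpha = 1` is plain additive
*à trous* fusion, both used as test oracles.

Box-counting details: the window's grey values are rescaled globally to
$[0, 255]$; for each cell size $s = 2, \dots, \lfloor w/2 \rfloor$ the
window is partitioned into $\lfloor w/s \rfloor^2$ cells (remainder
rows/columns ignored so the count scales as $(w/s)^2$ exactly on flat
input), each contributing
$\lfloor \max/h \rfloor - \lfloor \min/h \rfloor + 1$ boxes with
$h = sG/w$, and the dimension is the least-squares slope of $\log N(s)$
against $\log(w/s)$. On a constant plane this yields 2.0 within the
0.1 tolerance the estimator is tested to.

## Quality indices

Spectral indices compare the fused product against the original MS; the
comparison resolution is not uniquely defined, so the package defaults to
upsampling the reference to the PAN grid (`compare_at = "pan"`) and also
offers degrading the fused product to the MS grid (`compare_at = "ms"`).
The resolution ratio $h/l$ defaults to $0.46/1.84 = 0.25$.

- **SAM** — mean over pixels of the angle between band vectors, in
  degrees; zero-norm pixels are skipped; the arccos argument is clamped
  to $[-1, 1]$.
- **Spectral ERGAS** —
  $100 \frac{h}{l} \sqrt{\frac{1}{n}\sum_i (rmse_i / \overline{MS_i})^2}$.
- **Spatial ERGAS** — the same form with the PAN as per-band reference.
  Whether the PAN should first be radiometrically adjusted per band is
  not standardised; the default moment-matches the PAN to each fused
  band (`pan_adjust = "matched"`), and `"raw"` is available.
- **FC** — the PAN and each fused band are cut into 8×8 tiles (a DCT
  block size in wide use; reflection padding if the image is not a
  multiple), each tile DCT-II transformed, and the Pearson correlation
  of all AC coefficients (DC excluded, so constant offsets are
  invisible) is pooled over tiles and averaged over bands.
- **Zhou** — 3×3 Laplacian (centre +8, neighbours −1) of each fused
  band and of the PAN, Pearson correlation, averaged over bands.
- **Q / Q8** — the universal image quality index
  $\frac{4\,\sigma_{xy}\,\bar x\,\bar y}{(\sigma_x^2+\sigma_y^2)(\bar x^2+\bar y^2)}$
  per band, averaged over bands. Some statements of the multi-band form
  sum band terms without a $1/n$ factor even though the reported values
  lie in $[0,1]$; the package normalises by the band count and documents
  this as a deliberate reading. The
  quaternion-based Q4-style construction is explicitly not used.
  Degenerate flat-in-both blocks score 1 if identical, else 0.
  `quality_map()` evaluates Q on non-overlapping blocks (default 64 px,
  minimum 8) giving a per-band grid that localises fusion failures.

`evaluate_fusion()` computes all six per band subset — `all`, `in_pan`
(bands mostly covered by the PAN range: 2–6), `out_pan` (1, 7, 8). The
in-PAN flag uses a majority-overlap rule because band 7 (770–895 nm)
touches 450–800 nm with a 30 nm sliver that does not make it a covered
band.

## Borda ranking

Each index ranks the algorithms (SAM and both ERGAS: lower is better;
FC, Zhou, Q: higher is better); the best of $N$ items receives $N$
points and the worst 1 — this weighting, rather than $N-1 \dots 0$, is
what makes the reference worked-example columns come out exactly. Group
scores sum the member indices' points. The default groupings are
spectral = {SAM, spectral ERGAS}, spatial = {FC, Zhou}, global = all
six. Spatial ERGAS is *excluded* from the default spatial group: the
reference spatial rank columns the package reproduces are arithmetically
consistent only with the {FC, Zhou} pair, although prose descriptions
sometimes list spatial ERGAS among the spatial indices;
`borda_groupings(spatial_includes_ergas = TRUE)` restores the
three-index grouping. Ties are never broken silently: the `high` policy
(default) awards all tied items the best contested rank's points, with
`low` and `average` as alternatives, and `rank_report()` flags joint
ranks. Reference global columns mix tie conventions case by case, so
only the non-tied spectral/spatial columns are treated as exactly
reproducible; the per-ecosystem global winners are checked as "attains
the maximal global score".

## The synthetic scene generator

`paint_truth_scene()` builds an eight-band truth image at the PAN grid
from hand-designed material signatures (vegetation peaking in the NIR,
water darkest in the NIR, bright spectrally-flat sand and buildings) and
archetype-specific geometry:

- *shrubland* — bare-soil matrix with dense random shrub ellipses 2–10
  PAN pixels across (~40 % cover, so the heterogeneity survives 4×
  decimation);
- *coastal* — ≥ 60 % water by construction, a wiggly shoreline with a
  wet-sand transition over ~12 % of the scene width, smooth depth-driven
  darkening offshore and gentle (±4 %) dune brightness ripples — the
  deliberately smoothest archetype;
- *mixed* — a lagoon, an axis-aligned building/road grid and a rippled
  dune field.

A shared 8 % multiplicative white-noise texture plus a smooth
illumination field give every material fine-scale detail for the PAN to
carry. `degrade_to_pair()` then applies the reduced-resolution (Wald)
protocol: per-band Gaussian MTF blur (gain 0.35 at the decimated grid's
Nyquist), block-mean decimation, additive Gaussian noise (s.d. 1 % of
the band mean by default), and a PAN formed as the overlap-weighted sum
of truth bands 2–6 (weights proportional to each band's wavelength
overlap with 450–800 nm: $(60, 70, 40, 60, 40)/270$) blurred by the PAN
MTF (gain 0.15 at its own Nyquist). The MTF gains are nominal
literature-style values. Everything is driven by one integer seed
(`withr::with_seed`, with the noise stage offset by a fixed constant so
painting and degradation draw independent streams).

What this emulates: the resolution ratio, band layout, PAN spectral
coverage, sensor-like blur, and three contrasting levels of scene
complexity, with a true high-resolution reference available. What it
does not: radiative transfer, bathymetric optics, BRDF, sensor noise
statistics beyond additive Gaussian, registration error, or the actual
spectra of real land covers. Tests passing on these scenes therefore
validate the *algorithms and indices*, not claims about real-imagery
index values, which are out of reach without the commercial data.

## Numerical choices and degenerate inputs

- Interpolation operators are sparse matrices with half-sample
  reflection; this makes constant planes exactly invariant and block-mean
  decimation of an upsampled image conserve each band's global mean to
  machine precision — both are tested.
- Moment matching a zero-variance source to a varying reference is an
  error; matching flat to flat returns the reference level.
- HCS leaves zero-norm pixels at zero (their spectral direction is
  undefined); the substituted intensity is clipped at zero because a
  radius cannot be negative.
- The *à trous* reconstruction identity is enforced to $10^{-9}$
  relative in tests; the decomposition is exact by construction
  (differences of successive approximations).
- Problem sizes in the test-suite and acceptance runs use 16–64-pixel MS
  scenes (64–256-pixel PAN grids) and 128–512-pixel planes where a
  geometry contract requires it; these sizes were chosen as the smallest
  at which every scale-dependent component (two wavelet levels, 27-pixel
  fractal windows, 64-pixel quality-map blocks) is exercised
  non-trivially.

## Known limitations

- The TIFF writer in the underlying binding stores unit-range samples
  only, so exact round trips use the ENVI float64 format; TIFF reading
  is unrestricted.
- Q8 is the band-mean universal quality index, not the hypercomplex Q4
  generalisation.
- FIHS intensity weights for 8-band imagery and the HCS intensity
  matching are not uniquely standardised; both are configurable rather
  than asserted.
- The fractal-map weighting makes WAT⊗FRAC conservative on synthetically
  smooth scenes (low $\alpha$ nearly everywhere), so on the generator's
  output it injects less PAN detail than on real textured imagery — the
  behaviour is by design and visible in the spatial indices of the
  acceptance run.
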