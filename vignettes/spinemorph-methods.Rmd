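---
title: "Shape descriptors and morphology clustering for dendritic spines: models, parameters and numerical choices"
author: "spinemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinemorph methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

# The problem

Dendritic spines — the micrometre-scale protrusions that carry most
excitatory synapses — change shape under physiological and pathological
conditions; amyloid toxicity (an in vitro Alzheimer's disease model) shrinks
heads and elongates necks. Classical scalar metrics (length, volume, head
width) describe size more than shape. `spinemorph` implements two
whole-shape descriptors for triangulated spine surface meshes and the
statistical pipeline that asks whether a control and a treated spine
population occupy morphology space differently:

* a **spherical-harmonics (SphHarm) descriptor**: the spine surface,
  expressed as a radius function over directions from an interior center,
  projected onto the real spherical-harmonics basis;
* a **Light-Field (LF) descriptor**: binary silhouettes of the mesh from
  five fixed observation points, each encoded by Zernike moments on the
  unit disk;
* **k-means clustering** of descriptor feature spaces with cluster-count
  diagnostics, and per-cluster **Agresti–Caffo** plus overall
  **chi-squared** separability statistics between the two groups.

A parametric generator of spine-like meshes (mushroom, thin, stubby,
filopodia) supplies all fixtures and demo populations: no microscopy-derived
meshes are redistributed with the package.

# Canonical pose and the interior center

Real spherical harmonics are not rotation invariant, so every spine is first
moved to a canonical pose (`orientSpine()`). The junction region — the rim
where the spine attaches to its dendrite — defines it: the least-squares
plane through the junction vertices is rotated so its normal lies along +y
with the spine body on the positive side, and the remaining freedom (a
rotation about y) is fixed by putting the direction of largest xz-variance
on z. Two sign conventions make the pose fully deterministic: the body sits
at positive y, and the in-plane principal direction is chosen so the third
moment of the projections is non-negative (ties broken toward +z). The
junction centroid is placed at the origin. With these conventions a rotated
and translated copy of a spine reproduces the reference pose to machine
precision, which the test suite checks over random rigid motions.

The origin of the spherical coordinate system is the **internal center**:
the point of the shape skeleton nearest the center of mass. Spines are not
star-shaped from an arbitrary point; centering the coordinate system deep
inside the solid minimizes directions in which a ray crosses the surface
more than once. The skeleton is computed discretely: the solid is voxelized
by ray-parity (default pitch: bounding-box diagonal / 64), a 26-neighbour
chamfer distance transform is computed, and skeleton candidates are the
occupied voxels whose distance value is maximal within their
26-neighbourhood (the discrete medial-axis ridge). This is simpler than
iterative morphological thinning, is resolution-controlled through the
pitch, and satisfies the defining property everywhere we rely on it: for a
sphere it returns the center, for a cylinder a point on the axis, and for a
bent tube whose center of mass lies outside the solid it returns an interior
point. If the mesh is thinner than the pitch the rasterization comes back
empty and the function asks for a halved pitch rather than guessing.

# The radial tabulation and its ambiguities

`radialTabulation()` casts one ray per sampled direction from the center and
records the distance to the **farthest** intersection. The open design
question here is what to do when a ray crosses the surface more than once; taking the outer
envelope preserves the head outline — the morphologically dominant feature —
at the cost of bridging over concavities, and `multiHit = "first"` is
available for the opposite convention. The fraction of multi-hit rays is
reported as a star-shapedness diagnostic (`multiHitFraction`; typically
< 0.05 for our fixtures) and rays that hit nothing are dropped and counted.
More than 50% misses aborts the tabulation as degenerate. Raw ray hits are
used as-is; no interpolation between directions is performed.

# Spherical-harmonics encoding

Directions are drawn uniformly by the Monte-Carlo scheme (3-D standard
normals, normalized). With the tabulated radii $f(\theta,\phi)$ (divided by
their maximum, stored as `scale`, so descriptors are size invariant) the
coefficients are the projection sum

$$a_{lm} = \frac{4\pi}{|S|} \sum_{(\theta,\phi)\in S}
  f(\theta,\phi)\, Y_{lm}(\theta,\phi),$$

over all degrees $l < L$ and orders $|m| \le l$, packed in $(l, m)$
lexicographic order into a vector of length $L^2$ (the file contract of
`writeSphHarmCSV()`). The basis is the real (tesseral) orthonormal one
without the Condon–Shortley phase, evaluated through the stable normalized
associated-Legendre recurrence; orthonormality is verified against
Gauss–Legendre × trapezoid product quadrature to below $10^{-6}$.

Defaults are $L = 10$ (100 coefficients) and $N = 140$ sampling directions,
the grid-search optima for spine meshes; `gridSearchSphHarm()` reproduces
that search on any mesh set, flagging the plateau onset (smallest parameter
whose mean accuracy is within 5% of the best — the plateau cutoff is the
package's own choice and is configurable).

**Estimator variance, and why it matters.** The Monte-Carlo sum has
per-coefficient standard deviation $f_{\mathrm{rms}}\sqrt{4\pi/N}$ — about
$0.30\,f_{\mathrm{rms}}$ at $N = 140$ and $0.022\,f_{\mathrm{rms}}$ at
$N = 10^5$. Summed over the $L^2$ basis functions this produces a pointwise
reconstruction noise of $\sigma \approx f_{\mathrm{rms}}\sqrt{(L^2-1)/N}$,
i.e. reconstructions at the default $N = 140$ are noise-dominated, and even
at $N = 10^5$ the reconstructed radius of a perfect sphere fluctuates by a
few percent. Tests and the acceptance script therefore distinguish
regimes: coefficient-level checks use dense sampling ($N = 4\times10^5$,
recovering band-limited shapes to < 2% relative L2 error), while
statistical checks at $N = 140$ rely on the coefficients only through
between-spine contrasts, which survive the noise. It is worth noting that
$N = 140 \approx L^2 = 100$ is exactly the sample count at which a
least-squares fit of the truncated expansion becomes well-posed;
`encodeSphHarm(method = "lsq")` implements that variant, which recovers
band-limited functions exactly at small $N$, for users who want low-noise
reconstructions. The projection sum remains the default.

# Reconstruction

`reconstructSphHarm()` starts from an icosphere (default 4 subdivisions,
2562 vertices — enough that tessellation error sits below the Monte-Carlo
error) and moves every vertex at angles $(\theta, \phi)$ to the radius
$\sum a_{lm} Y_{lm}(\theta,\phi)$, scaled and translated back into the
original frame. Truncation ringing can drive the radius negative for thin
shapes; such vertices are clamped to $10^{-6}\cdot$`scale` and counted in
the `clamped` attribute instead of failing, since thin spines are a known
limitation of a radial representation. Approximation accuracy is measured
by the symmetric Hausdorff distance: surface samples of each mesh (always
including all vertices, plus area-weighted random samples, so the estimate
is monotone in the sample count at fixed seed) against the exact
point-to-triangle distance of the other.

# The Light-Field descriptor

After the same orientation and internal-center steps, the mesh is enclosed
in a sphere of radius $2r$ ($r$ = largest vertex radius about the center)
and observed from five fixed points: the three principal orthogonal
projections (+z, +x, +y) and two diagonal positions, at (zenith, azimuth) =
$(0,0)$, $(\pi/2,0)$, $(\pi/2,\pi/2)$, $(\pi/3,\pi/3)$ and
$(2\pi/3,\pi/3)$. Each view is an orthographic projection of all faces onto
the image plane, rasterized as filled triangles into a binary image
(default 256×256; a convergence check confirms the area fraction is stable
to 1% against 512×512). In-plane camera roll would change the real parts of
the moments, so it is pinned: image "up" is the world z-axis projected into
the view plane (world x for the top view, which looks along z).

The silhouette is inscribed into the unit disk via the minimal enclosing
circle of its foreground pixels (computed exactly with Welzl's algorithm on
the convex hull), which removes translation and scale. Zernike moments are
then

$$a_{mn} = \frac{n+1}{\pi}\sum_{x^2+y^2\le 1} f(x,y)\,
  V^{*}_{mn}(\rho,\theta)\,\Delta A,$$

for radial orders $n \le M$ (default 10) and $0 \le m \le n$ with $n - m$
even — 36 moments per view, 180 per spine; negative orders are conjugates
and are not stored. The $(n{+}1)/\pi$ factor and the per-pixel area element
$\Delta A$ are the standard normalization (a full disk has $a_{00} = 1$);
`normalization = "plain"` gives the bare double sum, which differs only by
per-$(n,m)$ constants and leaves every invariance property intact. Feature
vectors are the per-view real parts or moduli (`lfRealFeatures()`); moduli
are invariant to in-plane rotation and are the default, being the better
choice for clustering. `reconstructSilhouette()` inverts the truncated
expansion onto a pixel grid (threshold 0.5 of the maximum) for visual
assessment; a full 3-D reconstruction from five silhouettes is out of
scope.

# Clustering and separability statistics

`assembleFeatures()` stacks per-spine descriptor vectors, optionally
appending the one scalar size metric retained alongside the size-invariant
descriptors — the mesh volume — and drops (and reports) spines whose
descriptor chain failed. k-means (best of 20 restarts, seeded) provides the
clustering; `chooseK()` reports inertia and mean silhouette over a k-range,
surfacing both the elbow (largest second difference of inertia) and the
silhouette argmax without a silent tie-break. Dimensionality reduction to 3
components by PCA, t-SNE (perplexity 30, capped at $(n-1)/3$) or UMAP (15
neighbours, min_dist 0.1) is available and always seeded; hyperparameters
are recorded choices for reproducibility, not fitted values.

Separability between the control and treated groups is tested exactly as a
best-performance table row is built: per cluster, a one-versus-rest
Agresti–Caffo test compares the cluster membership rate between groups —
adjusted proportions $\tilde p_i = (x_i+1)/(n_i+2)$, z statistic from the
adjusted standard error, two-sided normal p — and one Pearson chi-squared
test (uncorrected, $k-1$ df) compares the whole cluster distribution.
Implementing the per-cluster test as one-vs-rest membership proportions
reproduces the published worked examples to two significant figures
(p = 0.037 and 0.0008 from counts back-derived from the printed
percentages at group sizes 279/271). Raw p-values are reported, as in the
original analysis; a Holm-adjusted column is emitted alongside, clearly
labeled. The uncorrected chi-squared choice is corroborated by the exact
identity $\chi^2 = z^2$ against the unadjusted two-proportion test on 2×2
tables.

**Feature scaling.** `assembleFeatures()` defaults to z-scoring, the safe
general choice for mixed-magnitude feature tables. For the SphHarm
coefficient space specifically, the separability study in the acceptance
script clusters **raw** coefficients (+ volume): by Parseval's identity,
Euclidean distance on the coefficient vector equals the L2 distance between
the radial functions — the canonical shape metric — whereas z-scoring
inflates the many near-zero high-order coefficient columns (which at
$N = 140$ carry mostly estimator noise) to unit variance and buries the
morphological signal under them.

# The synthetic-spine generator

`makeSpine()` builds a watertight surface of revolution about the spine
axis: a flat junction disk at $y = 0$ (its rim is the junction region), a
cylindrical neck of radius $r_n$ and length $\ell_n$, and an ellipsoidal
head (equatorial radius $r_h \ge r_n$, elongated along the axis by the
eccentricity factor) joined where the head cross-section equals the neck
radius and closed at an apex. Gaussian jitter along the local radial
direction (junction disk excluded, so the rim stays planar) provides
surface roughness. Class defaults (lengths in µm) are chosen to match the
classical archetypes: mushroom ($r_h = 0.45$, $r_n = 0.12$,
$\ell_n = 0.5$), thin ($0.18/0.08/1.0$), stubby ($0.40/0.32/0.05$),
filopodia ($0.08/0.08/1.2$, eccentricity 2 — a headless tapered
protrusion). The cylinder-plus-ellipsoidal-cap volume has a closed form
(`spineAnalyticVolume()`) used as the mesh-volume oracle.

`generatePopulation()` draws classes from a per-group mixture (default
0.4/0.3/0.2/0.1 mushroom/thin/stubby/filopodia in both groups), jitters the
class parameters lognormally (sd 0.15) for within-class diversity, and
applies the treated-group effect: head radii ×0.7 and neck lengths ×1.4 —
volume-reducing and elongating by construction, the morphological direction
reported for amyloid-treated spines. Everything is deterministic given the
population seed, with per-spine RNG streams derived by hashing the spine id
so that results do not depend on dataset order.

**What the generator does and does not emulate.** It reproduces the class
structure, the size scale, within-class parameter spread, surface
roughness, and a two-group morphological shift of controllable size. It
does not reproduce segmentation artifacts, junction irregularity, curved
necks, or the continuum of intermediate morphologies in real data — so
passing separability tests shows the pipeline recovers a planted effect of
realistic size and direction, not that it would detect any particular
biological effect.

# Study sizes and numerical choices

Test-suite and acceptance-script problem sizes are the package's chosen
study conditions: orthonormality on 200×400 (sphere) and 400×400 (disk)
quadrature grids; the sphere fixed point at $N = 10^5$; band-limited
recovery over 5 shapes at $N = 4\times10^5$ with truncation-monotonicity
over 20 seeded fixtures at $N = 2\times10^4$; Hausdorff validation against
an exhaustive all-vertex/all-triangle oracle on 10 small random meshes; and
the separability study at 100 spines per group over 20 population seeds
with a 500-permutation null calibration. Monte-Carlo tolerances in tests
are derived from the estimator's standard error (bounds at 3–4.5σ) rather
than round numbers.

Degenerate inputs are handled explicitly: open meshes fail the watertight
check before any chain step ("decomposition not possible"), empty
silhouettes and empty spherical samples raise errors, negative
reconstruction radii clamp with a report, and constant feature columns pass
through z-scoring centered but unscaled.

# Known limitations

* Thin, strongly curved spines violate the star-shape assumption; the outer
  envelope rule and the multi-hit diagnostic make the failure visible but
  the radial representation fundamentally limits them.
* The Monte-Carlo projection at the default $N = 140$ is noisy (see the
  variance analysis above); treat per-spine reconstructions at that setting
  as qualitative, or use dense sampling / the least-squares variant.
* The discrete skeleton depends on the voxel pitch; very thin necks need a
  finer pitch than the default.
* t-SNE and UMAP embeddings are seeded but algorithm-version dependent;
  PCA is the reproducible default for cross-machine comparisons.
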