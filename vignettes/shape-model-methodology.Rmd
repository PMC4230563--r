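---
title: "Building statistical shape models of organ surfaces and generating synthetic populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building statistical shape models of organ surfaces and generating synthetic populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapepop)
```

## The problem

Adaptive radiotherapy workflows need many plausible organ geometries —
for segmentation atlases, re-planning studies, and analyses of organ
deformation — but a clinic typically has only a handful of daily
segmentations per patient (of the order of 15 repeat scans). `shapepop`
fits a statistical shape model to such a small training set of closed
organ surfaces (bladder-, rectum- or intestine-like) and then draws
arbitrarily many new surfaces that are statistically representative of
the training variability.

The model is a point distribution model (PDM). Every training surface is
represented by the same ordered set of $m$ corresponded surface points,
stacked into a $3m$-vector $X$. With training shapes $X_1,\dots,X_N$:

$$X = \bar X + P\,b, \qquad
  D = \frac{1}{N-1}\sum_{i=1}^N (X_i-\bar X)(X_i-\bar X)^\top, \qquad
  D\,p_q = \lambda_q\,p_q,$$

where $P$ holds the leading eigenvectors ("deformation modes") of the
covariance $D$ and $b$ is the coefficient vector. The density of each
training coefficient $b_q$ is modelled as a 1-D Gaussian mixture

$$p_\mathrm{mix}(b_q) = \sum_{l=1}^{r} w_l\, \mathcal N(b_q;\, \mu_l, S_l),$$

fitted by EM, and new coefficients are drawn by inversion sampling
($W = F^{-1}(u)$ with $u$ uniform on $(0,1)$ and $F$ the mixture CDF),
giving new geometries $X_\mathrm{new} = \bar X + P\,W$.

## The pipeline

`shape_model()` runs five stages. All lengths are millimetres.

**1. Alignment.** Every training surface is mapped into the reference
surface's frame by a per-axis scaling plus translation (no rotation),
estimated by moment matching: the transformed centroid and per-axis
vertex standard deviations equal the reference's. This automates an
otherwise interactive step deterministically; an `isotropic` switch uses
one common factor instead. Rationale for per-axis as the default: it is
the more general member of the scaling family and reduces to the
isotropic case when the data call for it.

**2. Reference NURBS surface.** The reference mesh is cut into axial
contours (default spacing 2.5 mm, the slice thickness of typical
cone-beam CT), each contour is oriented counterclockwise, seeded at its
maximum-x point and resampled uniformly by arc length to `n_u` points
(default 36), and a cubic tensor-product B-spline surface is lofted
through the stack: periodic (closed) around the contours, clamped along
the superior–inferior axis, interpolating every resampled contour point.
The poles are closed by appending one degenerate contour collapsed to an
apex at each end. Two numerical choices matter here:

* *Apex placement.* The apex is placed by extrapolating the squared mean
  ring radius in $z$ with a quadratic through the three extreme slices —
  exact for quadric caps (spheres, ellipsoids) — clamped to within 0.1–3
  slice spacings of the extreme slice for robustness. A fixed half-slice
  offset underestimates rounded caps by several percent of the radius.
* *v-parameterisation.* Slice parameters follow the averaged 3-D chord
  length between consecutive resampled rings rather than the $z$ spacing
  alone. Near a rounded apex the surface profile behaves like
  $\sqrt{z_0 - z}$, which is singular when parameterised by $z$; chord
  length stays regular and the error concentrated at the cap rows
  disappears; the sphere-loft test holds the maximum radial error below
  0.5% of the radius, which the z-parameterisation cannot meet.

Weights are initialised to 1 throughout, so the surface is a non-rational
B-spline unless weights are supplied.

**3. Correspondence.** The reference surface is resampled on a fixed
`param_grid()` (default 50 × 50 = 2500 points; u uniform on $[0,1)$, v on
$[0,1]$ including the poles). For each resampled point the corresponding
point on an aligned training mesh is found in two stages: cast the line
through the point along the reference surface normal, intersect it with
the target triangles whose centroids lie within 5 mean edge lengths of
the point's closest-point foot, and take the nearest intersection within
half the target's bounding-box diagonal; if no admissible intersection
exists (or the normal is degenerate, as at the poles) fall back to the
plain closest point. The underlying closest-point search examines every
face, edge and vertex exactly (closed-form point-triangle minimisation);
ties go to the lowest face index so results are deterministic.

**4. Surface matching.** The reference NURBS is deformed onto each
corresponded target point set through `n_substeps = 10` intermediate
targets $X_1 + (X_2 - X_1)\,j/n$ — small steps avoid local minima — and
within each substep the control points are updated by damped
(0.8), Tikhonov-regularised ($\lambda = 10^{-6}$, trace-scaled) linear
least squares on the B-spline collocation system $B\,\Delta C = \Delta
X$, iterated until the surface moves less than 1 mm/1000 per iteration
(at most 50 iterations; non-convergence is reported in the result, never
thrown). The deformation is linear and order-independent; per-point
greedy updates were rejected for being order-dependent. Correspondence
is established once against the final target and interpolated linearly
for the substeps. Pole cap rows are tied to single free points so the
surface cannot open, and the degrees and knot vectors are untouched, so
all matched surfaces share one NURBS topology. Because the residual is
re-evaluated every iteration, the iteration converges to the
unregularised least-squares solution; exactly representable targets
(e.g. translations) are matched to solver precision.

**5. Statistics.** Matched surfaces are resampled on the shared grid,
giving corresponded shape vectors; the PDM eigenpairs are computed from
the $N\times N$ Gram matrix (the covariance itself, at $3m \times 3m$,
is never materialised — the equivalence is a tested property, not an
assumption). Modes are retained up to 90% cumulative variance by
default, an explicit `k` overrides. Eigenvector signs are canonicalised
(largest-magnitude component positive) so results do not depend on the
linear-algebra backend or the training order. One Gaussian mixture per
retained mode is fitted by EM (tolerance $10^{-8}$, at most 500
iterations, quantile-split initialisation plus 5 perturbed restarts, a
variance floor of $10^{-8}\times$ the sample variance), with the
component count $r \le 3$ chosen by BIC; the modes are treated as
independent 1-D densities because PCA decorrelates them. Sampling
inverts the mixture CDF by vectorised bisection to machine precision
($|F(F^{-1}(u)) - u| < 10^{-10}$). Sampled coefficients are not
truncated.

## Worked example

```{r example, eval = FALSE}
pop <- make_population(n = 15, preset = "bladder", seed = 101)
fit <- shape_model(pop$meshes, seed = 101)
fit
summary(fit)
plot(fit)                       # eigenvalue scree with cumulative curve
cohort <- simulate(fit, nsim = 100, seed = 7, type = "mesh")
```

## What the synthetic generator emulates — and what it does not

No real segmentations ship with the package, so `make_population()`
plays the role of the training data: `N` deformed instances of a smooth
closed organ-like base surface (a superellipsoid bladder, a bent-tube
rectum, a lobed intestine), with variability concentrated in a few known
deformation modes plus small i.i.d. vertex noise. Defaults mirror the
emulated imaging setting where they are known — 15 instances, 2.5 mm
slice spacing, mode coefficient SDs of 8, 5, 3, 2, 1 mm, 0.3 mm noise.
The base mesh resolution (40 × 24, edge length ≈ 4 mm) is the package's
own choice: it preserves the statistical structure of the population,
which is what the pipeline consumes, without the cost of voxel-level
(≈ 0.6 mm) surface sampling.

The ground-truth modes are radial fields — a smooth scalar profile times
the unit radial direction (inflation, a superior–inferior gradient,
lateral ovalisation, anterior tilt, a superior bulge; see
`mode_field_basis()`). Radial was a deliberate identifiability choice:
closest-point correspondence observes only the normal component of
surface motion, so a tangential mode (a twist, say) produces identical
corresponded point sets and is unrecoverable by any method of this
family. An optional bimodal law for mode 1 (two symmetric components,
means two component-SDs from zero, total SD preserved) exercises the
mixture-density stage.

Passing tests on these populations therefore demonstrate that the
pipeline recovers deformation statistics that are *normal-observable and
non-affine*; they do not certify behaviour on real contours with
segmentation error, sliding organs, or topology changes, none of which
the generator produces.

## Identifiability and the recovery experiment

Three structural facts shape how ground-truth recovery is assessed
(each verified empirically during development):

1. *Alignment absorbs affine variation.* Scaling + translation moment
   matching removes each mode's affine content before PCA sees it;
   uniform inflation, in particular, is mostly a scaling and is largely
   normalised away. The generator therefore offers `moment_neutral =
   TRUE`, which subtracts from every mode field its first-order effect
   on the centroid and per-axis variances, making the population
   alignment-invariant by construction.
2. *Correspondence observes normal motion.* The recoverable part of a
   mode field is its projection onto the reference surface normals, so
   the recovery oracle is the normal-projected true field.
3. *The poles are degenerate.* At the two cap rows the parameterisation
   collapses, normals vanish and correspondence falls back to closest
   point; recovery there is dominated by the cap construction rather
   than by data. Principal angles are therefore evaluated over the
   regular part of the grid ($v \in [0.1, 0.9]$).

Under those conditions (N = 15, zero noise, mode SDs 3–1.2 mm) the
recovery test asserts that the subspace spanned by the first five
eigenvectors matches the true mode subspace with every principal angle
below 10 degrees, and passes with a wide margin. Without the three
qualifications the largest angle plateaus above that threshold
regardless of amplitude — a property of the method, not of the
implementation.

## Degenerate inputs, tie-breaks, tolerances

* Mesh validation merges duplicate vertices within $10^{-9}$ mm, drops
  zero-area faces, and requires closed orientable genus-0 surfaces for
  training (Euler check $V - E + F = 2$); holes are an error, never
  filled.
* Slice planes that graze a pole can cut sliver loops: if the extra
  loops of a slice are below 20% of its dominant loop's perimeter the
  dominant loop is kept; if even the dominant loop is below 10% of the
  organ's largest section the slice is dropped as debris; several
  comparable substantial loops are an error (non-tube topology).
* Closest-point ties take the lowest face index; contour seeding uses
  the maximum-x vertex; both remove the respective ambiguity
  deterministically.
* EM restarts on component collapse (variance below the floor);
  all-equal samples are only admissible for $r = 1$.
* All randomness flows from one integer seed (population, EM restarts,
  sampling); refitting with the same inputs and seed is bit-identical.

## Problem sizes and defaults

The study-condition configuration — 15 training surfaces at mesh
resolution 40 × 24, a 50 × 50 resampling grid, 36-column lofts, 10
substeps — fits and samples in well under a minute on one CPU, and is
the configuration both the acceptance script and the end-to-end tests
use. Property tests use smaller spheres and grids since the properties
they check are resolution-independent.

## Known limitations

* Rotation is deliberately outside the alignment family; training data
  must arrive in a roughly common orientation.
* Modes are modelled as independent 1-D mixtures; joint non-Gaussian
  dependence across modes is not captured.
* Tangential deformation is invisible to the correspondence model (see
  above) — a limitation inherited from closest-point matching, shared
  by the whole model family.
* Generated surfaces are not checked for global self-intersection;
  `cohort_to_meshes()` flags instances that fail closure validation or
  have non-positive volume, which catches gross folding only.
* Per-patient vs pooled modelling is the caller's choice: fit one model
  per patient's scans, or pool several patients into one training list.
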