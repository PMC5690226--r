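---
title: "Population-learned deformation models for DIR validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-learned deformation models for DIR validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(deformgen)
```

## The problem

Deformable image registration (DIR) between a radiotherapy planning CT and
the daily CT scans acquired over a treatment course produces a deformation
vector field (DVF) — a per-voxel displacement — whose accuracy is hard to
assess because the true voxel-level correspondence is unknown.
Contour-based surrogates (Dice, surface distance) only probe organ
boundaries, and spline-based mathematical phantoms deform in ways unlike
real anatomy.

`deformgen` implements a population-based alternative: learn a statistical
model of anatomical variation from DVFs observed across a patient cohort,
sample new, anatomically plausible deformations from the model, apply them
to a reference CT to create artificial planning/daily image pairs whose
voxel-level deformation is known exactly, and score a DIR algorithm against
that ground truth.

## The model

Each training DVF on a common $X \times Y \times Z$ grid is vectorized
(component-major: LR block, then AP, then SI, each block with the first
grid axis fastest) into a column $d_t \in \mathbb{R}^{3V}$.  For $N$
training columns the model is the mean $\bar d = \frac1N \sum_t d_t$
together with the leading eigenpairs $(\lambda_j, \phi_j)$ of the sample
covariance

$$\Sigma = \frac{1}{N-1}\sum_{t=1}^{N} (d_t - \bar d)(d_t - \bar d)^{\top}.$$

$\Sigma$ is $3V \times 3V$ (about $0.6\,\mathrm{M} \times 0.6\,\mathrm{M}$
at $64 \times 64 \times 48$) and is never formed.  `fit_shape_model()` works
with the $N \times N$ Gram matrix $G = C^{\top} C/(N-1)$ of the centered
columns $C$: nonzero eigenvalues of $G$ and $\Sigma$ coincide, and
$\phi = C w / \lVert C w \rVert$ maps Gram eigenvectors $w$ to covariance
eigenvectors.  Eigenvalues below $10^{-12}\lambda_1$ are treated as zero
(the numerical rank of an $N$-sample Gram matrix); each mode's sign is
fixed by making its largest-magnitude entry positive so fits are
reproducible across linear-algebra backends.

The retained mode count $\hat T$ is the smallest number of leading modes
whose eigenvalue sum reaches $\alpha$ percent of the total variance.  The
compactness of the representation is summarized by the variation-space
reduction $100\,(N - \hat T)/N$ (`space_reduction()`).

New deformations are sampled as $d = \bar d + \sum_j b_j \phi_j$ with
independent Gaussian weights $b_j \sim \mathcal N(0, \lambda_j)$ subject to
a Mahalanobis bound $\sum_j b_j^2/\lambda_j \le D_{max}^2$.  The bound is
enforced by rejection sampling of the whole weight vector, which preserves
the Gaussian shape inside the acceptance region; per-coordinate clipping or
radial rescaling would not.  A radial-rescaling fallback triggers only
after 1000 consecutive rejections (pathologically small $D_{max}$ with many
modes).  `D_max = 0` returns the mean deformation.

## The workflow

`build_interpatient_model()` mirrors the cohort workflow: rigid
(translation-only, cross-correlation) pre-alignment to a chosen reference
subject, cropping to the common space, demons registration of every other
planning volume to the reference (DVFs "EF"), and a model fit at
$\alpha = 90$.  `build_intrapatient_model()` registers each daily volume to
its subject's planning volume, transfers each resulting DVF into the
reference space through that subject's EF field (`transfer_dvf()`, a
per-component image resampling that deliberately applies no Jacobian
reorientation), pools them, and fits at $\alpha = 95$ — the higher level
reflecting the larger, more distinct training set.  The reference subject
is a configuration choice, not automated: the clinical criterion
(weight/BMI cohort median) is not computable from images.

`generate_artificial_pair()` follows the generation sequence exactly:
sample `DE` from the inter-patient model ($D_{max} = 3$ by default); invert
it iteratively and warp the reference planning volume by the inverse to get
the artificial planning volume; then for each requested intra-patient
$D_{max}$ (defaults 2, 3.5, 4.5) sample `DT`, transfer it through `DE`
(`DI <- transfer_dvf(DT, DE)`), invert `DI`, and warp the artificial
planning volume by the inverse to get the artificial daily volume.  `DI`
is the stored voxel-level ground truth: a DIR run from daily to planning
should reproduce it, and `run_validation_experiment()` scores exactly that
via `error_map()` and per-structure statistics.

## The registration engine

The demons variant is symmetric-force: with $f$ the fixed image, $\tilde m$
the currently warped moving image and $g = \nabla f + \nabla \tilde m$,
the per-iteration update is

$$u = \frac{(f - \tilde m)\, g}{\lVert g \rVert^2 + \kappa^2 (f - \tilde m)^2},$$

smoothed with `sigma_update` (fluid-like), magnitude-capped at `step_cap`
(2 mm), accumulated, and the accumulated field smoothed with `sigma_field`
(diffusion-like), inside a 3-level coarse-to-fine pyramid.  Choices that
matter:

* $\kappa$ defaults to the reciprocal of the mean voxel spacing.  This is
  the standard demons normalization: it makes the two denominator terms
  dimensionally commensurate ($\mathrm{HU^2/mm^2}$) and balances them at
  moderate contrast, giving usable step sizes.  Scaling $\kappa$ with image
  gradient magnitude instead (an option via `intensity_scale`) suppresses
  the update by orders of magnitude on CT-range intensities.
* Smoothing sigmas are specified in mm at the finest level and applied in
  voxel units at every pyramid level, so coarse levels regularize over
  proportionally larger physical extents.  The accumulated-field diffusion
  is also the only mechanism that propagates displacement into flat,
  gradient-free regions (organ interiors); the default
  `sigma_field = 4 mm` (2 voxels in-plane at 2 mm spacing) was chosen so a
  2-voxel rigid translation of a smooth test object is recovered to well
  under half a voxel, while a smooth 4 mm deformation of the head phantom
  is recovered to ~0.3 mm mean error inside the body.  `sigma_update`
  defaults to 1.5 mm.
* Intensities are clamped to $[-1000, 2000]$ HU before registration so
  isolated extreme values (dental-artifact-like) cannot dominate the force.
* `demons_params()` defaults to a (50, 30, 20)-iteration schedule, enough
  for image alignment; the model-building pipeline stages default to
  (80, 50, 30), because training DVFs feed a covariance model where
  incomplete convergence appears directly as spurious eigen-variance.
* The engine is fully deterministic: identical inputs give bit-identical
  fields.

The force term is isolated in one internal function so a different demons
family member can be swapped in.

## DVF algebra

`invert_dvf()` uses the fixed-point iteration
$v_{n+1}(x) = -d(x + v_n(x))$ (trilinear, edge-clamped sampling), stopping
when the largest per-voxel change falls below `tol` (0.01 voxel) or at
`max_iter` (50).  The iteration is a contraction when every partial
derivative of every displacement component is below 1; the returned field
carries residual statistics and a `converged` flag, and warns rather than
fails when the residual stays above `10 * tol`.  `compose_dvfs()` provides
the matching pull-back composition ($c(x) = b(x) + a(x + b(x))$), used both
to verify inversions and to chain deformations.

## The synthetic population

The paper-scale cohort data behind this method (planning plus ~30 daily
CTs for each of 12 patients) is not publicly available, so the package
ships a fully synthetic study population with known ground truth
(`make_population()`).  Its defaults are the package's study conditions:

* **Grid** $64 \times 64 \times 48$ at $(2, 2, 3)$ mm — large enough for a
  3-level pyramid, small enough that one demons registration takes seconds.
* **Anatomy** (`make_reference_phantom()`): a soft-tissue body ellipsoid
  (0 HU) in air ($-1000$), a mandible-like bone arc and a spine-like bone
  column ($+1000$), and two low-contrast parotid-like ellipsoids
  ($+40$ HU), with additive Gaussian noise (SD 10 HU).  The population
  generator also enables a smooth deterministic soft-tissue intensity
  modulation (amplitude 50 HU, `texture_amplitude`): real CT soft tissue is
  not flat, and without some large-scale interior intensity structure an
  intensity-driven registration has nothing to anchor interior voxels to —
  with a featureless interior the recovered interior motion is pure
  regularization fill-in, which is a property of the phantom, not of the
  method.  `texture_amplitude = 0` (the bare default) gives exactly the
  four nominal intensities, which the unit tests rely on.
* **Latent deformations**: `K_inter = 2` between-subject and `K_intra = 3`
  between-fraction modes, built from seeded Gaussian noise smoothed at
  32 mm, windowed to the (feathered) body — anatomy deforms, air does not —
  orthonormalized, and scaled by one common factor so all modes carry equal
  variance per unit weight (per-mode peak scaling would make the latent
  spectrum uneven and rank recovery ambiguous).  Weight SDs are 5 mm
  (inter) and 6 mm (intra), which yield parotid-mean daily deformations of
  roughly 2–9 mm — the organ-scale range reported for head-and-neck
  treatment courses.  A foldover guard redraws any weight vector whose
  combined field would exceed half the smallest body radius in peak
  magnitude or 0.7 in any displacement-component derivative (beyond that
  the mapping approaches non-invertibility); the latent distribution is
  therefore Gaussian with bounded support, the anatomical counterpart of
  the $D_{max}$ bound.
* **Direction convention**: the stored ground-truth fields are expressed in
  the direction a registration estimates (subject-to-reference,
  daily-to-planning, pull-back); each anatomy is produced by warping with
  the iteratively inverted field.  This makes the registration-direction
  training DVFs exactly low-rank.  The alternative (low-rank structure in
  the forward warp) leaves the estimated DVFs equal to *inverses* of
  low-rank fields, which carry quadratic off-subspace terms that are a
  property of the construction, not of the learning method.
* Every exposed volume carries independent noise; noise-free companions
  (`*_clean`) are stored so regeneration checks can be exact.

What passing tests on this population do **not** show: performance on real
anatomy with weight loss, tumor shrinkage, neck flexion, dental artifacts,
appearing/disappearing air cavities, or deformation at spatial frequencies
above what a 32 mm-smooth basis contains.  The phantom suite validates the
learning machinery and the end-to-end bookkeeping, not clinical
registration accuracy.

## Measurement conventions in the recovery experiment

The parameter-recovery experiment (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) fits the intra-patient model on the default
population and checks (i) that the eigen-scree drops by at least a factor
5 after mode 3, and (ii) that the top-3 fitted subspace aligns with the
generator basis with mean principal-angle cosine above 0.8.  Two
conventions, fixed before the experiment was first run:

* Subspace alignment is computed after restricting both bases to body
  voxels.  Intensity-driven registration cannot observe displacement in
  uniform air, so a full-grid comparison would grade the phantom's air
  region rather than the method.
* Even with perfect registration the three fitted eigenvalues are not
  equal: they are order statistics of a 3-dimensional Wishart sample
  (40 draws), which spreads $\lambda_1/\lambda_3$ to roughly 2–3.  The
  scree-ratio threshold applies to $\lambda_3/\lambda_4$, the gap between
  the weakest true mode and the strongest error mode.

Problem sizes used throughout: 8 subjects, 5 fractions each (40 intra
training DVFs, 8 inter), the default grid above.  The full experiment —
48 demons registrations plus transfers and fits — runs in a few minutes on
one CPU.

## Numerical details worth knowing

* Grids are axis-aligned only; world = origin + index · spacing; index
  order (LR, AP, SI); displacements always in mm.
* `warp_volume()` is pull-back (output at $x$ samples input at
  $x + d(x)$); out-of-grid samples take `fill` ($-1000$ for CT, 0 for
  masks, nearest-neighbour for labels).  DVF algebra (`invert_dvf`,
  `compose_dvfs`) clamps to the edge instead, which avoids injecting
  spurious boundary vectors; `transfer_dvf` follows `warp_volume` (fill 0)
  because it is defined as component-image resampling.
* `rigid_align()` searches integer-voxel translations only, with ties
  broken toward the smaller magnitude, then lexicographically;
  `crop_to_common_space()` uses the *intersection* of the aligned boxes
  (the other reading of a "common space", the union, would require
  inventing data outside acquired volumes).
* Two empty masks make `dice()` an error rather than 0 or 100: an
  undefined metric should surface, not hide, a data problem.
* `mean_surface_distance()` extracts surfaces as labeled voxels with a
  six-connected unlabeled neighbour and averages the two directed mean
  nearest-surface distances; distances use the anisotropic spacing.
* Model files are a directory of little-endian float64 arrays plus JSON
  metadata recording the grid, $\alpha$, $\hat T$ and the frozen
  vectorization order; round-trips are bit-exact.

## Known limitations

* The demons variant is a documented symmetric-force stand-in for the
  dual-force algorithm used with the original cohort; published accuracy
  numbers for that algorithm are out of scope.
* `transfer_dvf` resamples displacement components as scalar images
  (no gradient reorientation), faithful to the workflow it implements but
  not differential-geometrically exact for large inter-patient warps.
* Artificial volumes inherit the reference volume's noise through warping;
  independent per-volume noise injection is available in the generator but
  is not applied to artificial pairs, whose smooth warped noise signature
  is a known limitation of this class of methods.
* The sampler assumes the training DVFs are well described by their first
  two moments; heavy-tailed or multi-modal cohort variation would violate
  the Gaussian assumption behind both the mode-weight sampling and the
  interpretation of $D_{max}$ as a Mahalanobis radius.
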