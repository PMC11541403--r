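---
title: "Statistical shape modeling for nasal prosthesis design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modeling for nasal prosthesis design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(noseforge)
```

This vignette documents the models, algorithms and numerical choices
behind `noseforge`, in the spirit of a methods section: what is computed,
under which assumptions, and why the open design decisions were settled
the way they were. It states no empirical result that the package's tests
and acceptance script do not themselves compute.

## 1. The morphable face model

The statistical engine is a point-distribution model over faces in
vertex-wise correspondence. Training shapes are aligned by generalized
Procrustes analysis — translation and rotation only by default; uniform
scale normalization is available but off, because prosthesis work is
metric and a 10 % larger face needs a 10 % larger nose. Stacked vertex
coordinates are then decomposed by PCA:

\[ x = \mu + U\,\mathrm{diag}(\sigma)\,c, \qquad c \sim \mathcal N(0, I), \]

with orthonormal modes \(U\) and per-mode standard deviations \(\sigma\)
in mm. Coefficients are stored standardized (units of SD), so the ridge
regularizer used in fitting is a plain squared norm and a coefficient
bound of "3" means three standard deviations for every mode.

**Rank truncation.** By default the retained rank is the smallest one
carrying 99.9 % of the population variance. The tail modes of a PCA are
dominated by numerical noise (for our synthetic population their SDs are
micrometres); keeping them makes the inverse problem of fitting
ill-conditioned without adding representable anatomy. The `rank` argument
overrides the rule.

**Flexibility augmentation.** To reconstruct shapes outside the training
span, smooth deformation modes can be appended: a squared-exponential
covariance \(k(p, q) = v\, e^{-\|p-q\|^2 / 2\ell^2}\) acting independently
per coordinate axis, approximated at low rank by a Nystrom eigendecomposition
on a vertex subsample with out-of-sample extension. Defaults are
\(\ell = 30\) mm and \(v = 1\) mm² with 50 added modes — chosen so the
added flexibility is sub-centimetre and smooth at face scale; the length
scale is about the width of a nasal sidewall, i.e. large enough not to
introduce high-frequency artifacts the optical scan could not support.
The combined basis is re-orthonormalized by an eigendecomposition inside
the joint subspace, which preserves the base span exactly (every base
sample remains representable) and yields non-increasing mode SDs.

**Posterior conditioning.** `posteriorModel()` conditions the coefficient
distribution on observed vertex positions with isotropic Gaussian noise;
the posterior mean and covariance eigenmodes form a new model of the same
class. Posterior mode variances are bounded by the prior ones (Loewner
ordering of the posterior covariance), which the tests check.

## 2. Fitting a defect-masked scan

The affected region is erased from the scan before any fitting, so defect
geometry cannot influence the morphing. Fitting then iterates:

1. **Correspondences.** Every usable model vertex takes its closest point
   on the partial scan. Pairs are rejected when the distance exceeds
   `corrMaxDistance` (5 mm), the normals disagree by more than
   `corrMaxNormalAngle` (60°), the closest feature lies on an open rim, or
   the closest point falls within a 1.5 mm band of the rim — the band
   keeps noisy crater-edge geometry from anchoring correspondences.
   Vertices inside the region that is to be reconstructed (the nose area,
   known once on the reference topology) are excluded from the search
   altogether: their true counterparts were amputated, so any
   correspondence they find on the surrounding skin is wrong by
   construction and would drag the fit.
2. **Coefficient solve.** A ridge-regularized least-squares problem in
   standardized coefficient space, clipped to `coeffBound` (3 SD). The
   first three iterations use point-to-point residuals for capture range;
   later iterations switch to point-to-plane residuals (projection on the
   target normal), which removes the tangential-sliding bias of
   closest-point matching — without it, coefficient recovery on full
   scans stalls at a small but systematic error.
3. **Rigid refinement.** A closed-form orthogonal-Procrustes update on
   the accepted pairs, coupled with the shape update each iteration.
   Initialization comes from named anatomical landmarks (at least three,
   non-collinear).

Iteration stops when the correspondence RMS changes by less than
`convergenceTol` (0.01 mm default) or at `maxIterations` (50). All
defaults are package choices, exposed in `fitConfig()` and in the flat
YAML run configuration; none are claimed to be clinically calibrated.

## 3. The geometry kernel

No mesh-processing library with booleans, offsets or signed distances is
available in this R stack, so the package carries its own kernel (Rcpp):

- **Closest points and signed distance** via an AABB tree with exact
  point-triangle distances; the sign comes from the angle-weighted
  pseudonormal of the closest feature, which is exact for watertight
  meshes. On-surface queries report the non-negative sign. For open
  sheets the same query yields a side-signed distance plus a flag marking
  queries whose closest feature lies on the open rim.
- **Offsets and booleans by implicit resampling.** Fields are sampled on
  a regular grid (the origin is shifted by an irrational fraction of the
  pitch so nodes never coincide with mesh planes) and the zero isosurface
  is extracted by marching tetrahedra on the Freudenthal 6-tet cube
  decomposition with edge-keyed vertex welding — watertight by
  construction, also on concave regions, which is why offsets are not
  implemented by per-vertex normal displacement. The cost is chamfering
  of sharp features at the grid pitch; `resolution` (mm) trades accuracy
  for time. Solidifying an open sheet bounds the solid at the rim by the
  boundary-normal frontier (no rounded bead is added beyond the rim), so
  a hemispherical test shell matches its analytic volume.
- **Measurements.** Wall thickness is defined operationally: area-weighted
  surface samples, a ray cast along the inward normal, distance to the
  first opposite crossing, median over at least 1000 samples. The median
  makes the protocol robust to rim and side-wall samples.

## 4. The prosthesis/mold protocol

The design stage reproduces an 11-step clinical CAD protocol with the
printed settings as defaults: prosthesis wall 6 mm, mold closure gap
0.3 mm, mold shell wall 4 mm. The remaining parameters are package
choices: blend band width 3 mm and depth 0.5 mm (the border ring is sunk
half a millimetre into the skin with a cosine falloff, guaranteeing the
subtraction leaves a thin feathered edge), densification target 0.5 mm,
10 smoothing iterations for the inner and connecting surfaces, 30 mm face
backing depth (the scan sheet must become a volume before it can be
subtracted), 10 mm flange extent.

The two traditionally manual steps are parameterized operations rather
than interactive ones: border sculpting is the blend band, nostrils are
capped cylinders; externally edited meshes can be substituted at the
pipeline level, mirroring the pause-and-edit checkpoint of clinical
practice without requiring it.

**Mold construction.** The PM's skin-facing and visible sheets are
separated implicitly by a parting field (inside the face solid, or deeper
than one prosthesis wall behind the nose sheet). Each mold half is the
set of points within one shell wall of the PM on its side of the parting,
extended by a flat flange ring that follows the prosthesis edge curve
(the blended rim of the nose model) at a per-angle radius; the anterior
ring is offset by the closure gap along the parting normal. A least-squares
plane through the rim defines the flange frame — flat flanges
are an approximation on a curved face, recorded as such. The anterior
half is additionally carved against the *extracted* posterior's distance
field, which is 1-Lipschitz, so the closure gap holds across the
feather-edge discontinuity of the raw parting field; any residual
sub-pitch undercut from isosurface interpolation is removed by projecting
short-clearance vertices back to the exact gap. Shell thickness, closure
gap, cavity fidelity (95th-percentile PM-to-shell distance) and a casting
simulation (the volume enclosed by the clamped mold) are all measured by
the test suite on a toy case with known analytic geometry.

## 5. The synthetic face fixture

Licensed clinical face databases cannot ship with the package, so the
fixture generator emulates one: height-field faces on a shared 96 × 96
grid (guaranteeing vertex-wise correspondence), an ellipsoidal head with
a parametric nose — six interpretable parameters (nose length 50 ± 4 mm,
width 34 ± 2.5 mm, bridge height 8 ± 1.2 mm, tip projection 18 ± 2.2 mm,
nostril radius 5 ± 0.4 mm, face breadth 140 ± 4 mm), drawn independently
per face with a mandatory seed. Landmarks (exocanthi, glabella, pogonion,
cheeks) sit at analytically known grid positions away from the nose, so
they survive a simulated rhinectomy. Rim noise of 0.1 mm emulates the
resolution of a structured-light scan; the CT route voxelizes the face at
an anisotropic spacing and re-extracts the skin isosurface.

One generator property deserves emphasis: the nasal parameters also shape
nearby *intact* anatomy — glabella prominence scales with bridge height,
the upper-lip region with tip projection and nose length, paranasal cheek
fullness with nose width. This emulates the face–nose correlation of real
populations, which is the entire statistical basis of reconstruction from
the remaining face; with strictly nose-confined parameters the conditional
distribution of the erased region given the intact face would be the
prior, and no method could beat the population mean. Passing tests
therefore show that the pipeline *exploits* such correlations correctly;
they cannot show how strong those correlations are in real faces, where
the shared anatomical factors are weaker and noisier. The generator also
does not emulate texture, expression, scanning holes away from the
defect, or non-Gaussian shape variation.

## 6. Problem sizes and numerical choices

Tests and the acceptance script run the implicit-surface stages at a
0.5 mm pitch on the toy case (0.1 mm for the boolean-oracle grids,
0.3 mm for the shell-volume check) and 0.5–0.6 mm for the synthetic
end-to-end run; the population size is 40 faces at the default 96 × 96
topology. These sizes keep a full run in the tens of minutes on one CPU
while leaving every tolerance dominated by the method, not the grid.
Degenerate inputs are rejected explicitly (empty meshes, non-watertight
boolean operands, all-vertex defect masks, collinear landmarks, coarser
than 5 mm CT spacing); zero-iteration smoothing and empty nostril
specifications are identities; a boolean whose result is empty returns an
empty mesh rather than failing, since `a \ a` is a legitimate query.

## 7. Known limitations

- Booleans and offsets chamfer sharp edges at the sampling pitch; the
  protocol's surfaces are smooth at that scale, but a sub-0.1 mm feather
  tip is below the default resolution.
- The flange is flat by construction; on strongly curved faces the
  closure surface deviates from the skin and the achieved gap is
  reported, not assumed.
- The fit assumes a rigid patient: no expression neutralization,
  texture, or multi-scan fusion.
- Coefficient recovery to 0.05 SD holds for the variance-truncated
  model; modes at or below scanner noise are not identifiable from
  surface data by any method.
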