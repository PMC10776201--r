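---
title: "Quantifying tumor growth direction against white-matter microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor growth direction against white-matter microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthtrack)
```

## The problem

Diffusely infiltrating gliomas tend to migrate along myelinated axons
(perineural satellitosis), so the *direction* in which a contrast-enhancing
lesion grows between two scans carries biological information.  Given two
coregistered tumor masks at two timepoints and a diffusion-tensor template
supplying the local white-matter orientation, `growthtrack` estimates a
dense growth deformation field, computes the voxel-wise angle between
growth vectors and fiber directions, and summarizes each patient as a
nine-bin angle histogram over 0–90° with *parallel* (0–20°) and
*perpendicular* (70–90°) fractions.  A cohort is then characterized by the
mean fractions, a paired t-test between them with Cohen's *d*, Lilliefors
normality checks, one-way ANOVAs against MGMT methylation status, and a
tumor frequency map.

Because clinical two-timepoint data of this kind are not publicly
shareable, the package ships a synthetic phantom generator whose growth is
known analytically.  Every quantitative claim in this vignette is checked
by the test suite or recomputed by `scripts/acceptance.R`; nothing is
asserted that the code does not itself compute.

## The model and its pieces

### Growth deformation field

The baseline mask (timepoint 1, the *moving* image) is registered to the
follow-up mask (timepoint 2, *fixed*) with a cubic B-spline free-form
deformation.  Binary masks have no intensity gradients, so the metric is
the sum of squared differences between *signed Euclidean distance maps* of
the masks, clamped at ±`dmax_mm` (default 10 mm) so that only a band
around the two surfaces drives the fit.  A bending-energy penalty
(squared second differences of the control lattice, weight `lambda` =
0.01) keeps the transform smooth.  The optimizer is L-BFGS-B on the
control-point displacements with analytic gradients; convergence is a
relative metric change below 1e-5 or `max_iter` = 50 iterations.
Optimization runs inside a region of interest around the union of the two
masks, and the returned field is identically zero outside that dilated
union — the deformation is local to the lesion, as a growth field should
be.

The reported field follows the growth convention: at each voxel of the
follow-up grid it is the displacement (mm, world frame) carrying the
baseline material point to that voxel, so vectors point outward for an
expanding lesion.

Two choices deserve comment:

* **Resolution levels.**  The `levels` parameter implements a classical
  multi-resolution pyramid (control spacing doubling per level, exact
  dyadic knot-insertion between levels), but the default is a *single*
  level at 8 mm control spacing.  On sphere-expansion phantoms the
  clamped-distance metric already attracts the solution from well beyond
  typical interscan displacements, while a 16–32 mm lattice cannot
  represent a localized expansion: its best fit is a smooth wrong field
  whose tangential component lies in the null space of the distance
  metric (surfaces slide along themselves), and finer levels inherit it.
  Measured on the r = 5 → 7 mm concentric-sphere phantom, the fraction of
  growth-region vectors within 15° of radial is 1.00 with one level and
  0.06–0.21 with two or three; the mean endpoint error is 0.19 voxels
  versus 0.8–1.1.  Extra levels remain available for large-displacement
  problems.
* **Mask-to-mask by default.**  The deformation is estimated from the
  masks themselves (distance-map SSD).  An alternative reading — register
  the surrounding scalar images with the tumor union *excluded* from the
  metric — is available as `metric = "ssd_image_excluded"` and through the
  pipeline's `mode$mask_to_mask` switch, but it characterizes the
  surrounding tissue rather than the lesion's own shape change, so it is
  not the default.

### Fiber directions from the tensor template

The template is six component volumes (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).  An
analytic symmetric 3×3 eigensolver (trigonometric eigenvalues, projector
eigenvectors with two refinement passes) yields the principal eigenvector
and fractional anisotropy

FA = sqrt(3/2) · ‖λ − λ̄‖ / ‖λ‖

per voxel.  A voxel is *valid* when the leading eigenvalue is separated
from the second by more than 1e-6 relative, the tensor is positive
semi-definite within tolerance, and FA ≥ `fa_min`.  Degenerate voxels are
flagged and counted, never raised as errors.  `fa_min` defaults to 0 — no
white-matter gate — because the clinical workflow this reproduces reports
no FA threshold; 0.2 is the conventional choice when one wants to restrict
to coherent white matter.  A `diagonal_only` mode (direction = axis of the
largest diagonal entry) exists for templates distributed as diagonal
components only; the full-tensor mode is the default since diagonals alone
cannot encode off-axis directions.

### Angles, bins, thresholds

Fiber directions are sign-ambiguous, so the angle between a growth vector
g and direction w is arccos(|g·w| / ‖g‖‖w‖) ∈ [0°, 90°], invariant to the
sign and scale of both.  Histogram bins are [0,10), [10,20), …, [80,90]
(the last bin closed; an angle of exactly 20° is *not* parallel, exactly
70° falls in the 70–80 bin).  Voxels entering the histogram are the union
of the two masks, gated by displacement magnitude > `eps_mm` (0.1 mm —
numerically-zero displacements have meaningless directions) and by fiber
validity; each exclusion is tallied by reason.  Each included voxel casts
one vote (`weighting = "count"`); magnitude weighting is available but
changes the estimand from "fraction of growing voxels" to "fraction of
displacement mass".  The direction field is matched to the deformation
grid by nearest-neighbour sampling, because unit vectors cannot be
linearly interpolated under sign ambiguity.

### The solid-angle null

If growth directions were uniformly random, the expected fraction in a bin
[a, b] is cos a − cos b: about 1.5% in 0–10° but 17.4% in 80–90°, with
parallel ≈ 6.0% and perpendicular ≈ 34.2%.  Two consequences matter.
First, any observed parallel fraction must be judged against this highly
asymmetric baseline, not against uniformity over bins; a cohort in which
the parallel fraction merely *equals* the perpendicular one is already
strongly parallel-biased relative to chance.  Second, a secondary maximum
in the 80–90° bin can arise purely from this solid-angle geometry, without
any biological perpendicular preference.  The package therefore defines
its positive finding directionally: `parallel_preference` in the cohort
summary requires the mean parallel fraction to *exceed* the mean
perpendicular fraction with a significant paired test.  A two-sided
rejection in the perpendicular direction under direction-free growth is
geometry, not biology, and the type-I-control simulations in the
acceptance suite count only spurious *parallel* detections.

### Cohort statistics

Per-patient parallel and perpendicular fractions are compared with a
classical paired Student's t-test (t = mean(d)/(sd(d)/√n), df = n−1,
two-sided p, Cohen's d = mean(d)/sd(d)).  Normality of both populations is
reported via the Lilliefors-corrected Kolmogorov–Smirnov test (D computed
in-package, p via the Dallal–Wilkinson approximation; a seeded Monte-Carlo
table covers n = 4) but never gates the t-test, mirroring the clinical
workflow.  MGMT ANOVAs exclude "unknown" patients — missingness is not a
level — and no multiple-testing correction is applied across the three
ANOVAs (the output records this).  Tumor growth rate is the specific
growth rate 100·ln(V2/V1)/days, which is fair across unequal scan
intervals; a linear variant is a config option.

## The synthetic phantom generator

`generate_fiber_field()` builds a template whose tensors are prolate with
principal direction following a uniform, radial, or curved pattern, and
whose FA equals `fa_target` *exactly* (eigenvalues solved in closed form,
default FA 0.5 and mean diffusivity 7e-4 mm²/s, typical white-matter
values).  `simulate_tumor_growth()` rasterizes the baseline sphere
(radius r1) and its anisotropic affine expansion
A = f_par·P + f_perp·(I − P) analytically per voxel centre — masks are
never produced by warping, so simulator correctness is independent of
registration correctness.

The analytic ground-truth deformation is the growth field of that affine
expansion evaluated on the follow-up grid, w(x) = (I − A⁻¹)(x − c) inside
the follow-up mask.  Defining the truth through the expansion map (rather
than radially, surface point to surface point) is what makes the
directional ground truth sharp: with f_perp = 1 every growth vector is
exactly axis-parallel, so a phantom grown at angle θ to the fibers puts
all its histogram mass in the bin containing θ, which is the property the
recovery tests assert.  A radial definition would spread the direction of
the very same mask pair over the full 0–90° range and no registration
could (or should) recover a single-bin histogram from it.

`simulate_cohort()` / `generate_cohort()` draw per-patient parameters from
a fixed seed plus the patient index: baseline radius r1 ~ U(5, 8) mm,
centre jitter ±4 mm, scan interval uniform integer 4–97 days and MGMT
labels in proportions 35/16/27 (the ranges of the clinical cohort this
emulates), grid 64³ at 1 mm.  A fraction `bias` of patients grows along
the local fiber direction (default factors 1.5 parallel / 1.1
perpendicular); the rest grow spherically
(`mode = "random_isotropic_vectors"` — the radial growth vectors of a
spherical expansion are isotropically distributed, and the expansion
factor (f_par·f_perp²)^⅓ matches the biased patients' volume change).

What the phantoms deliberately do **not** emulate: MR contrast and noise,
edema and infiltration beyond the mask, perivascular growth, mass effect
on the surrounding fibers, inter-scan acquisition differences, and
template-to-patient anatomical mismatch.  Passing tests therefore show
that the *measurement chain* — registration, eigen-analysis, angle
binning, statistics — recovers known directional structure at realistic
lesion scales; they cannot show that clinical growth is parallel to white
matter, nor validate the use of a population template in the presence of
tumor-displaced fibers.

## Numerical choices and degenerate inputs

* Distance transforms are exact Euclidean (lower-envelope algorithm),
  with anisotropic spacing support; signed distance is d_outside −
  d_inside, so boundary-shell values are within one voxel diagonal of 0.
* Affine registration (12 dof: translation, rotation, scale, shear about
  the fixed-volume centre) minimizes mean squared intensity difference by
  BFGS with finite-difference gradients over a 3-level image pyramid;
  degenerate parameter points return a large finite penalty so the line
  search can back off.  Self-registration returns the identity to 1e-3
  mm / 1e-4 rad; translations are recovered to ~0.2 mm and scales to
  ~1% on structured phantoms.
* Eigen ties: a relative gap below 1e-6 marks the direction invalid
  (isotropic and oblate-degenerate tensors have no meaningful principal
  direction).
* Empty growth-voxel sets raise a typed condition instructing the caller
  to report the patient as non-evaluable; the pipeline excludes such
  patients with a logged reason and aborts only if fewer than two
  evaluable patients remain.
* All tabular outputs format numbers at fixed precision, so reruns with
  the same seed are byte-identical.

## Problem sizes used in validation

The test and acceptance runs use 64³ grids (1 mm) for single-phantom and
biased-cohort checks (30 patients), and 48³ grids with r1 ~ U(4, 6) mm for
the 50-replicate × 15-patient direction-free cohorts used for type-I
control — small enough for a desk-scale run, large enough that lesions
span 10–16 voxels across and the histogram has thousands of voxels per
patient.

## Known limitations

* The B-spline transform is not guaranteed diffeomorphic; for the growth
  factors simulated here folding does not occur, but extreme expansions
  would need constraint or composition.
* Only SSD-type metrics are implemented; mutual information (needed for
  cross-modality registration) is out of scope.
* Tensor reorientation after affine template-to-patient registration uses
  the rotation factor of the polar decomposition (finite-strain); a
  no-reorientation mode exists for strict replication, but preservation
  of principal directions under large shears is approximate either way.
* The histogram treats voxels as independent votes; spatial correlation
  of neighbouring growth vectors is not modelled, so per-patient CIs on
  bin fractions would be anti-conservative and are deliberately not
  reported at the voxel level.

## A worked example

```{r example, eval = FALSE}
library(growthtrack)

# a 6-patient cohort, all growing along the fibers
co <- simulate_cohort(6, bias = 1.0, seed = 7)
dirs <- principal_direction_map(co$template)

res <- lapply(co$patients, function(p) {
  def <- nonlinear_register_masks(p$t1, p$t2)
  quantify_patient(p$t1, p$t2, def, dirs, patient_id = p$id,
                   interval_days = p$interval_days, mgmt = p$mgmt)
})
summarize_cohort(res)
```

On this seed the summary reports a mean parallel fraction of 38.4%
(95% CI 28.0–48.8%) against a mean perpendicular fraction of 10.3%
(95% CI 7.9–12.7%), paired t(5) = 5.65, p = 0.0024, Cohen's d = 2.31 —
the directional signal the phantoms were built with, recovered through
registration.
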