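# growthtrack

Quantifying the direction of tumor growth relative to white-matter
microstructure from two-timepoint MRI.

Diffusely infiltrating gliomas preferentially migrate along myelinated
axons (perineural satellitosis).  `growthtrack` measures this on imaging:
given binary tumor masks at two timepoints and a diffusion-tensor template
providing local fiber orientation, it

1. estimates a dense **growth deformation field** by B-spline free-form
   registration of the baseline mask onto the follow-up mask (SSD on
   clamped signed distance maps, bending-energy regularized, L-BFGS-B);
2. derives per-voxel **fiber directions** as the principal eigenvector of
   the tensor field, with fractional-anisotropy
   (FA = √(3/2)·‖λ−λ̄‖/‖λ‖) and eigen-gap validity masking;
3. computes voxel-wise **angles** Φ = arccos(|g·w|/‖g‖‖w‖) ∈ [0°, 90°]
   between growth vectors g and fiber directions w, bins them into nine
   10° bins, and reports the **parallel** (0–20°) and **perpendicular**
   (70–90°) fractions per patient;
4. runs **cohort statistics**: per-bin means with 95% CIs, a paired
   Student's t-test between parallel and perpendicular fractions with
   Cohen's d, Lilliefors (KS) normality, one-way ANOVAs against MGMT
   status, specific growth rate 100·ln(V2/V1)/days, and a tumor frequency
   map in template space.

Because such clinical data cannot be redistributed, the package includes a
first-class synthetic phantom generator (`simulate_tumor_growth`,
`simulate_cohort`, `generate_cohort`) producing two-timepoint masks whose
growth has a *known* angular relationship to a generated fiber template,
together with the analytic deformation field — the ground truth every
recovery test is scored against.  Under uniformly random growth directions
the expected fraction in bin [a, b] is cos a − cos b (parallel ≈ 6.0%,
perpendicular ≈ 34.2%), so the package's positive finding is directional:
a cohort shows a *parallel preference* only when its mean parallel
fraction exceeds the mean perpendicular fraction with a significant paired
test.

## A worked example

```r
library(growthtrack)

co   <- simulate_cohort(6, bias = 1.0, seed = 7)   # all along-fiber growth
dirs <- principal_direction_map(co$template)

res <- lapply(co$patients, function(p) {
  def <- nonlinear_register_masks(p$t1, p$t2)      # growth field, mm
  quantify_patient(p$t1, p$t2, def, dirs, patient_id = p$id,
                   interval_days = p$interval_days, mgmt = p$mgmt)
})
summarize_cohort(res)
#> <cohort_summary> n = 6 patients
#>   parallel  (0-20):  38.4% (95% CI 28.0-48.8%)
#>   perpendicular (70-90): 10.3% (95% CI 7.9-12.7%)
#>   paired t(5) = 5.647, p = 0.00242, Cohen's d = 2.31
#>   parallel preference: yes
```

The six phantoms were grown along their fiber template (semi-axis factors
1.5 parallel, 1.1 perpendicular); the summary shows the pipeline
recovering that bias through registration: 38.4% of growing voxels within
20° of the fibers versus 10.3% within 20° of perpendicular, a significant
paired difference.  Against the solid-angle null (6.0% vs 34.2%) both
numbers are strongly parallel-shifted.

Disk-based cohorts use the layout
`cohort/<id>/{t1_mask,t2_mask,t1_img,t2_img}.nii.gz` plus
`template_tensor.nii.gz` and `metadata.csv`; `run_pipeline()` (or the thin
CLI in `inst/cli/growthtrack.R`) drives the whole chain from a YAML config
and writes `patient_results.csv`, `cohort_summary.json`, a tumor frequency
map and a hashed run manifest.

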