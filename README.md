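# cdtmorph

Group morphometry and classification for diffusion MRI, built on the full
local diffusion geometry instead of scalar summaries.

Each voxel's **ensemble average propagator** (EAP) — the water-displacement
density P(**r**), Fourier-dual to the normalised diffusion signal
E(**q**) = S(**q**)/S₀ — is represented as a zero-mean Gaussian mixture
over a shared dictionary of axially symmetric diffusion tensors and
estimated from HARDI data by nonnegative ridge least squares. A control
population's EAP fields are fused into an **unbiased sharp template** in
two stages, each costing O(N) registrations: groupwise diffeomorphic
registration under the closed-form L2 mixture distance with
preservation-of-principal-direction (PPD) reorientation, then projection
of the intermediate average onto the orbit of a population member (the
template is a warped real image, not a blur). Every subject is then
registered to the template and the warp's local strain is summarised
voxel-wise by the **Cauchy deformation tensor**, CDT = √(JJᵀ), a symmetric
positive-definite matrix that is identity wherever the warp is locally a
rigid rotation. CDT fields are analysed on the SPD(3) manifold:
voxel-wise Fréchet means, **principal geodesic analysis** (PGA) on the
concatenated tangent space for dimension reduction (an ROI of 362 voxels
gives a 6·362 = 2172-dimensional problem, reduced to at most N−1
components), a permutation-calibrated tangent-space Hotelling test for
localisation, and a grid-searched leave-one-out **ν-SVM** (RBF kernel)
for patient-vs-control classification, with a DTI/FA baseline for
comparison. A synthetic HARDI phantom generator (64 directions,
b = 1000 s/mm², Rician noise, planted localized effects) provides ground
truth for every stage.

The methods vignette (`vignettes/cdt-morphometry.Rmd`) documents the
model, the numerical choices and the limitations.

## Worked example

```r
library(cdtmorph)

dict <- buildDictionary()                       # 46 orientations + isotropic
spec <- phantomSpec()                           # 32 x 32 x 16, SNR 20
eff  <- effectSpec(roi_lo = c(13, 7, 6), roi_hi = c(18, 12, 9),
                   shape_grid = spec$shape, warp_amplitude = 1.5)
pop  <- makeTwoClassPopulation(12, 12, spec, eff, seed = 11,
                               subject_warp = 1, dict = dict)
roi  <- effectROI(spec$shape, eff, margin = 2)

res <- runPipeline(lapply(pop$members, `[[`, "dwi"), pop$labels, roi,
                   dict = dict, seed = 11, n_perm = 200)
res$cdt_report
#> ClassifierReport: accuracy 0.8750, sensitivity 1.0000, specificity 0.7500
#>   selected r = 5 , g = 0.001 , nu = 0.111
res$table1
#>   biomarker accuracy sensitivity specificity
#> 1       CDT    0.875   1.0000000   0.7500000
#> 2        FA    0.750   0.8333333   0.6666667
sum(res$ttest$mask01)
#> [1] 83
```

The strain biomarker beats the orientation-blind FA baseline on the same
ROI and protocol, and 83 of the 800 ROI voxels reject the voxel-wise
null at p < 0.01 (the test suite verifies that such detections
concentrate on the planted block).

The run takes a few minutes on one core (template construction dominates:
12 control subjects × 4 registration passes). `res$ttest` holds the
voxel-wise manifold test with p < 0.05 / p < 0.01 masks over the ROI;
`writePipelineReport(res, "report.json", "table1.csv")` exports the
report. A thin CLI over the same functions lives in `inst/cli/cdtmorph`
(`simulate` and `run-all` subcommands).

The CDT report above is the package's desk-scale analog of the published
protocol; the original 68-subject cohort is not public, so its headline
figures are not reproduced here.

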