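---
title: "EAP templates and Cauchy deformation tensor morphometry"
author: "cdtmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EAP templates and Cauchy deformation tensor morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Single-tensor diffusion MRI (DTI) summarises each voxel by one Gaussian
and cannot resolve crossing fibers; scalar summaries such as fractional
anisotropy (FA) additionally discard all orientation information. For
group studies of neurodegeneration — the motivating application is
separating Parkinson's disease patients from controls using midbrain
diffusion data — this loses exactly the information where the pathology
may express itself. `cdtmorph` implements a pipeline that keeps the full
local diffusion geometry:

1. represent each voxel's ensemble average propagator (EAP) — the
   displacement probability density $P(\mathbf r)$, Fourier-dual to the
   normalised signal $E(\mathbf q) = S(\mathbf q)/S_0$ — as a zero-mean
   Gaussian mixture over a shared dictionary;
2. build an unbiased, *sharp* template of the control population's EAP
   fields by groupwise diffeomorphic registration followed by projection
   onto the orbit of a population member;
3. register every subject to that template and summarise the required
   deformation voxel-wise by the Cauchy deformation tensor (CDT)
   $\sqrt{JJ^\top}$, a symmetric positive-definite strain measure;
4. analyse the CDT fields on the SPD(3) manifold: Fréchet means,
   principal geodesic analysis (PGA) for dimension reduction, a
   permutation-calibrated tangent-space Hotelling test for localisation,
   and a grid-searched leave-one-out $\nu$-SVM for classification.

# The mixture representation

## Dictionary

Every subject's EAP field lives on one fixed dictionary of axially
symmetric diffusion tensors
$D_k = (\lambda_\parallel - \lambda_\perp)\,u_k u_k^\top + \lambda_\perp I$
on a geodesic hemisphere tessellation (default: the 46-direction
frequency-3 icosahedral tessellation), plus one isotropic atom. Defaults
are typical white-matter values, $\lambda_\parallel = 1.7\times10^{-3}$,
$\lambda_\perp = 3\times10^{-4}$, isotropic $2.0\times10^{-3}$ mm$^2$/s.
The EAP component of atom $k$ is $N(\mathbf 0,\, 2\tau D_k)$ with
effective diffusion time $\tau = \Delta - \delta/3 \approx 39.07$ ms for
the monopolar $\Delta/\delta = 42.4/10$ ms gradient timing the synthetic
acquisition emulates.

## Estimation

Per voxel the weights solve
$\min_{w \ge 0} \lVert A w - E \rVert^2 + \rho \lVert w \rVert^2$ with
$A_{ik} = \exp(-b_i\, g_i^\top D_k g_i)$, by Lawson–Hanson active-set
NNLS on the ridge-augmented system ($\rho = 10^{-3}$ by default), then
rescaling to $\sum_k w_k = 1$ so the mixture is a probability density.
Only the leading `max_components` weights (default 6) are kept: under
noise the active set spreads over near-collinear atoms, and truncation
both denoises and bounds the quadratic pair cost of the mixture distance.

## Distance

Image similarity is the voxel-wise $L^2$ distance between mixture
densities, which is closed-form for zero-mean Gaussians through
$c(A,B) = (2\pi)^{-3/2}\det(A+B)^{-1/2}$. For axially symmetric
components $C = pI + q\,uu^\top$ the determinant reduces to a scalar
formula in $(p, q, u_i^\top u_j)$, making the energy cheap enough to
evaluate at every voxel of every registration iteration. The closed form
is verified against brute-force 3D quadrature in the test suite.

# Registration and reorientation

Deformations are dense displacement fields $T(x) = x + d(x)$ in voxel
units, enforced diffeomorphic through $\det(I + \nabla d) > 0$. Warping
a mixture field interpolates the weight vectors trilinearly at $T(x)$
and reorients each component by the local Jacobian using preservation of
principal direction (PPD): the principal eigenvector maps to
$Fe_1/\lVert Fe_1\rVert$ and the eigenvalues — the component's shape —
are preserved exactly. For axially symmetric atoms PPD reduces to
rotating the axis to $Ju/\lVert Ju\rVert$. The forward frame $F = J$ is
the default; $F = J^{-\top}$ is available via a flag.

Because template averaging is defined weight-wise on the shared
dictionary, a warped field's reoriented components are reassigned to the
nearest dictionary orientation (`snap = TRUE`, a ~7–14 degree
discretisation at the default 46 directions); the exact per-voxel axes
are kept when `snap = FALSE`. The registration energy applies the same
snapping to both sides, which makes the discretisation consistent: a
field warped by the true deformation has (numerically) zero energy
against its warp, rather than a large orientation-mismatch floor that
would corrupt the gradient.

The optimiser is greedy fluid-style descent rather than full geodesic
shooting: per iteration the voxel-wise gradient of the squared mixture
distance with respect to the displacement is taken by central finite
differences (step 0.25 voxel; PPD is non-smooth at eigenvalue crossings,
so analytic differentiation through it is deliberately avoided),
normalised to a unit direction field (so flat and steep regions advance
at comparable rates), smoothed by a Gaussian of width `smooth_sigma`
(default 2 voxels — the standard practical stand-in for the inverse of
the $L^\dagger L$ regulariser, with $L$ a 27-neighbourhood Laplacian),
capped at `max_step` (default 0.4 voxel) and composed with the current
field. A step is accepted only if it keeps $\det J > 0$ everywhere and
decreases the total energy, so the energy trace is monotone by
construction. A 3-level multiresolution pyramid (block averaging by 2)
supplies the large-displacement basin. The volume penalty is the
log-determinant term $\lambda \log(\det J)(\det J - 1) \ge 0$, zero
exactly at volume preservation; $\lambda$ (default 0.05) is expressed in
units of the initial mean per-voxel data energy so its meaning does not
depend on the dictionary scale. The sign convention of this term is
chosen so it acts as a penalty under minimisation; the $\le 0$ variant
with the opposite ordering of the factors cannot be minimised.

On the standard recovery experiment (32³ textured phantom, smooth
synthetic warp of 2-voxel amplitude) the registration recovers the warp
with mean endpoint error ≈ 0.13 voxels; the acceptance suite asserts
< 0.5.

# Template construction

Stage one alternates (i) registering every subject to the current
average, (ii) re-averaging the warped, reoriented fields, and (iii)
unbiasing by composing all deformations with the inverse of their mean
displacement, so the average deformation stays near identity. It stops
when the population energy stops decreasing (default at most 3 outer
iterations; the joint minimisation has no published iteration rule, so
the count is a package choice and the energy trace is exposed). Stage
two registers each subject to the intermediate average and selects the
(subject, warp) pair of minimal data energy — ties broken by smallest
index — making the final template a *warped population member*: sharp by
construction, with the averaging blur removed. Both stages cost exactly
$N$ registrations per pass, which the package asserts with an internal
registration counter.

The convention for the final reorientation: the selected member is
warped by its registration deformation and PPD-reoriented by that
deformation's Jacobian, i.e. the template is expressed in template-space
coordinates with consistently reoriented mixtures. (The alternative
reading — reorientation by the inverse Jacobian with warping by the
inverse map — is the same operation applied from the opposite side; the
implementation performs warp and reorientation together, consistently.)

# CDT morphometry and manifold statistics

The Cauchy deformation tensor of a subject-to-template warp,
$\mathrm{CDT} = \sqrt{JJ^\top}$ (left stretch; the $J^\top J$ variant is
a flag), is identity wherever the warp is locally a rigid rotation and
captures local strain otherwise. CDTs live on the negatively curved
SPD(3) manifold, so Euclidean statistics are inappropriate; the package
uses the affine-invariant metric by default
($\mathrm{Log}_M X = M^{1/2}\log(M^{-1/2} X M^{-1/2})M^{1/2}$), with the
faster log-Euclidean metric as an option (on commuting data PGA under it
reduces exactly to PCA of matrix logarithms, which the tests exploit as
an oracle).

PGA concatenates all ROI voxels: tangent vectors at the voxel-wise
Fréchet means are whitened ($S = \log(M^{-1/2}XM^{-1/2})$) and
vectorised with off-diagonals scaled by $\sqrt 2$, giving a $6V$-dim
Euclidean space in which PCA is performed (the product-manifold reading:
a 362-voxel ROI gives $6 \times 362 = 2172$ dimensions, reduced to at
most $N-1$ components — 67 positive-variance components for 68
subjects). The voxel-wise group test is a Hotelling $T^2$ in the tangent
space at the pooled Fréchet mean, calibrated by label permutations
(default 1000; the seed is mandatory) because no parametric null is
assumed; masks are reported at uncorrected $p < 0.05$ and $p < 0.01$,
with Benjamini–Hochberg adjustment available behind a flag.

# Classification protocol

The $\nu$-SVM with RBF kernel $\exp(-g\lVert x-y\rVert^2)$ is evaluated
by leave-one-out over a grid: $g \in [0.001, 1]$ step 0.001, $\nu \in
[0.001, 0.90]$ step 0.001, and $r \in \{5, 10, \ldots, 65\}$ leading PGA
components (capped at the available $N-1$). `stride_factor` multiplies
the $g$ and $\nu$ steps (default 10 for desk-scale runs; 1 reproduces
the full protocol). Selection by the LOO accuracy itself replicates the
original protocol and is optimistically biased — the selected accuracy is
a model-selection maximum, not an unbiased error estimate; this is
deliberate, and the bias is shared by every method compared under the
same protocol (the FA baseline uses the identical grid and folds).
Features are z-scored on each training fold only (an unscaled flag
exists). Patients are the positive class. The grid scan visits cells in
ascending $(r, g, \nu)$ order with strict improvement, which realises
the smaller-$r$/-$g$/-$\nu$ tie-break and allows terminating at the
first perfectly classifying cell without changing the selected cell.

The solver is libsvm throughout: `looEvaluate()` goes through
`e1071::svm`, while the grid search calls e1071's registered training
routine directly to skip per-call data-frame overhead (hundreds of
thousands of 23-point fits); the two paths are asserted to produce
identical predictions, and `kernlab` serves as a further independent
cross-check in the tests.

The FA baseline fits a single tensor per voxel by weighted linear least
squares on log-attenuations (weights $E^2$), computes
$\mathrm{FA} = \sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert /
\lVert\lambda\rVert$ over the ROI, and runs the same $(g, \nu)$ grid
search on the raw FA vector (FA has no natural analog of the PGA
component count; a PCA-per-$r$ reduction mirroring the CDT pipeline is
available behind a flag).

# What the synthetic data emulate — and what they do not

`makePhantom()` emulates the acquisition geometry of the motivating
study — 64 electrostatically spread directions at $b = 1000$ s/mm², one
$b=0$ volume, Rician noise (default SNR 20 at $b_0$) — on a desk-scale
32×32×16 grid rather than 112×112×60, so the full pipeline runs in
minutes on one core. The layout has a single-fiber band, a 90-degree
crossing band and isotropic-dominated background, all modulated by a
smooth sinusoidal partial-volume texture: without texture, uniform
compartments are locally translation-invariant (the aperture problem)
and no registration could recover a warp there. Populations are
independently warped (default 1-voxel amplitude, 4-voxel smoothness,
zero at a boundary band) and independently noised copies; the planted
patient effect is a localized compressive warp and/or an in-place
rotation of fiber orientations inside a 6×6×4 block (≈144 voxels, the
same order as the study's 362-voxel midbrain ROI), placed inside the
single-fiber band so a pure reorientation provably leaves the FA map
unchanged. Two details of the rotation effect matter for that guarantee
and were found the hard way: the rotation is smoothly tapered (a sharp
orientation discontinuity at the block edge becomes, after warping and
interpolation, a genuine crossing-fiber partial volume that *lowers* FA —
orientation gradients are FA-visible even though orientations are not),
and it is applied antisymmetrically (−θ/2 to controls, +θ/2 to
patients), which makes the orientation-gradient statistics of the two
classes identical by construction while keeping the full between-class
orientation contrast for the mixture-based pipeline.

What passing these tests shows: the estimator, metric, registration,
template, manifold statistics and classifier interact correctly and the
planted effects are recovered end to end. What they do not show: realism
of anatomy, scanner artefacts (eddy currents, distortion, motion),
inter-subject biological variability beyond smooth diffeomorphisms, or
that the real-cohort discrimination figures would be reproduced — the
original cohort is not public, and no claim about it is made here.

# Numerical choices and degenerate inputs

* Attenuations are clamped to $(10^{-6}, 1]$; $S > S_0$ is physically
  impossible attenuation and is treated as noise. Multiple $b=0$ volumes
  are arithmetically averaged; $S_0 = 0$ voxels are masked out.
* Components below 1% of a voxel's weight mass are dropped inside the
  registration energy: they are negligible in the distance but dominate
  the pair count.
* Warped voxels with interpolated mass below 0.05 are treated as
  background rather than renormalised (renormalising near-zero mass
  would manufacture tissue).
* All-zero-weight voxels are undefined as densities; estimation falls
  back to the isotropic atom with a counted warning.
* The Fréchet fixed-point iteration is initialised at the closed-form
  log-Euclidean mean; non-convergence raises an error with the residual.
* Deformation inversion iterates $d^{-1} \leftarrow -d(x + d^{-1})$ and
  errors if the composition residual is not below 0.1 voxel.
* Degenerate PPD frames (isotropic components, eigenvalue ties) keep the
  component unchanged or complete the frame with any orthogonal vector —
  the reconstructed covariance is invariant to that choice.
* Pseudo-random generators are pure functions of (spec, seed); every
  stochastic stage takes an explicit seed.

# Known limitations

* Greedy compositive descent is not a geodesic-shooting LDDMM: it
  guarantees a diffeomorphism and monotone energy, not a distance-minimal
  path; symmetric/inverse-consistent registration is out of scope.
* Dictionary snapping discretises orientations at the tessellation
  resolution; studies needing finer angular contrast should raise
  `n_orient`.
* The replicated grid-search protocol selects by LOO accuracy itself;
  treat the selected accuracy as comparative, not as a generalisation
  estimate. A nested protocol can be built from `looEvaluate()` but is
  not the default, to match the replicated procedure.
* The manifold test is uncorrected by default (matching the reported
  thresholds); use the BH flag for discovery-rate control.
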