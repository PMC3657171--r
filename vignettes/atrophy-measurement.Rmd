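---
title: "Measuring gray-matter atrophy from serial MRI: models, phantoms and trial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gray-matter atrophy from serial MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Gray matter (GM) shrinks measurably over 6–12 months in Alzheimer's
disease — on the order of 2% of its volume per year, against roughly
0.5%/yr in healthy aging. A treatment trial that uses the GM atrophy
*rate* as its endpoint needs that rate measured with as little variance
as possible: the per-arm sample size scales with the measurement variance
through

n = (u + v)² · 2σ² / (μ₁ − μ₂)²,

so halving the measurement SD quarters the trial. This package
implements three ways of turning a pair of T1-weighted volumes into an
atrophy rate, and the statistics layer that turns group summaries of
those rates into sample sizes:

1. **Segmentation and subtraction** (`segment_tissues()`,
   `binarize_gm()`, `seg_subtract()`): segment each time point into
   CSF/GM/WM, threshold the GM probability at 0.5, subtract the two
   binary-mask volumes. Errors of the two independent segmentations add.
2. **Fluid registration + Jacobian integration** (`fluid_register()`,
   `jacobian_integrate()`): estimate a dense deformation taking the
   repeat image onto the baseline and integrate `1 − det J` of that
   deformation over the baseline GM mask. One consistent deformation
   replaces two independent segmentations, which is where the variance
   advantage comes from.
3. **Brain boundary shift integral** (`bbsi_window()`, `bbsi()`): for
   whole-brain (parenchymal) change, integrate the clipped intensity
   difference of the aligned, intensity-normalized pair over a one-voxel
   band around the brain boundary, scaled by an intensity window placed
   inside the CSF–GM transition.

Everything upstream of the measures — 12-dof affine registration
(`register_affine()`), tissue-based intensity normalization
(`normalize_intensity()`), cropping with the thrice-dilated brain mask
(`crop_dilated()`) — is in the package as well, so `run_pair()` executes
the whole chain on a pair of NIfTI volumes.

## The fluid model

The nonlinear stage models the deformation as a compressible viscous
fluid. At each iteration the *body force* is the analytic gradient of
global normalized cross-correlation (NCC) with respect to the per-voxel
displacement; the velocity field solves

μ ∇²v + (μ + λ) ∇(∇·v) = −F,

and the displacement advances along the velocity with a step capped at
`max_step` (default 0.3) voxels, composing each increment with the
running field. If the incremental field's minimum Jacobian determinant
drops below `regrid_threshold` (default 0.5) the incremental field is
reset (a *regrid*) while the total transformation keeps accumulating, so
the final `det J` — the per-voxel volume-change factor — always refers to
the total composed map and stays positive.

Numerical choices worth knowing:

* **Solver.** The operator is discretized with central differences under
  impermeable free-slip boundary conditions (zero normal displacement,
  zero normal derivative of tangential components). Component *i* is
  then exactly diagonalized by a mixed sine/cosine basis (sine along its
  own axis, cosine along the others), giving an independent 3×3 system
  per frequency; `solve_velocity()` inverts those directly
  (`solver = "fft"`). A red-black successive over-relaxation solver
  iterates the identical finite-difference system (`solver = "sor"`) and
  agrees with the direct solver to its iteration tolerance — that
  agreement, plus the closed-form modal solution for a single-harmonic
  force, is how the solver is tested. Strict zero-displacement walls
  would couple the grad-div term across the whole basis; the free-slip
  condition is what makes the exact diagonalization possible, and the
  force is zero near the crop-box walls in practice.
* **Viscosities** default to μ = 1, λ = 0; λ = 0 decouples nothing in
  the operator (the grad-div term keeps μ + λ) but is the conventional
  neutral choice.
* **Pre-smoothing.** Both images are smoothed with a σ = 1 voxel
  Gaussian (`smooth_sigma`) before the similarity and force are
  evaluated; the recovered field is applied to the *unsmoothed* repeat
  image for the final windowed-sinc rendering. Without this, the NCC
  landscape under trilinear warping is dominated by interpolation
  ringing at tissue edges and greedy iteration chases artefacts:
  on phantoms with a known 2.0% GM loss the unsmoothed flow drifts to a
  measured ~2.9%, while the smoothed flow converges stably to ~2.0–2.1%.
* **Stopping.** Iteration stops when the mean body-force norm over the
  mask falls below `force_threshold`, when no admissible step strictly
  improves the correlation (stagnation — reported in
  `$stop_reason`), or at `max_iter` (default 30; on 64³ phantoms the
  integrated GM loss is within ~0.05 pp of its plateau by then, with
  diminishing returns from further iterations). The published exit threshold
  5×10⁻⁸ for the mean body force is available as a preset
  (`fluid_params(force_threshold = 5e-8)`), but its normalization is
  tied to the original implementation; the default threshold here is
  calibrated so that identical pairs (whose force is exactly zero) exit
  on the first evaluation while realistic pairs run to stagnation.
* **Step control.** A strict-improvement line search halves the step up
  to 8 times and doubles the starting step after each success (capped at
  `max_step`), which makes the accepted NCC sequence strictly monotone.

## The digital phantom

`make_phantom()` builds a three-tissue head: an outer CSF shell, a
convoluted cortical GM ribbon (an ellipsoidal shell whose radius carries
a sinusoidal angular perturbation of order `harmonics`), a WM core and
two deep-GM blobs. Intensities are tissue means (defaults 20/70/110 for
CSF/GM/WM, a T1-like ordering) plus Gaussian noise (default SD 2, i.e.
5% of the 40-unit class gap), modulated by a smooth polynomial bias
field (default ±5%). The default grid is 64³ at 2 mm isotropic for fast
replicate studies; `preset = "native"` switches to the acquisition-like
anisotropic geometry (0.9735 × 0.9735 × 1.5 mm).

Two features matter for what the phantom can and cannot validate:

* **Partial volume** (`pv_grid`, default 3): tissue fractions per voxel
  are estimated from 3×3×3 analytic subvoxel label samples, and the
  noise-free intensity is the fraction-weighted tissue mean. This is the
  phantom's stand-in for the scanner point-spread function, and it is
  essential: with pure voxel-centre labels (`pv_grid = 1`) boundary
  voxels sit at pure-tissue intensities, a subvoxel boundary shift never
  moves any posterior across the 0.5 threshold, and
  segmentation-subtraction reads ~0 regardless of the true loss.
* **Known atrophy** (`apply_known_atrophy()`): the follow-up image is
  produced by an analytic, curl-free radial displacement concentrated at
  the outer cortical surface, with the scale factor solved so the true
  fractional loss of the target region (GM ribbon, or GM+WM parenchyma
  for `mode = "brain"`) hits the requested value within 0.1% relative.
  The oracle integrates the closed-form Jacobian of the analytic map
  over the region support enumerated at 4× grid refinement, inverting
  the map pointwise by fixed-point iteration; folding (det J ≤ 0) is
  checked over the whole field. Because the displacement is known in
  closed form, the same ground truth scores Jacobian integration,
  segmentation-subtraction and the BBSI on identical pairs.

What passing phantom tests does **not** show: the phantom has Gaussian
(not Rician) noise, a smooth low-order bias field rather than coil
profiles, perfectly known brain masks, no motion or gradient-distortion
artefacts, and an atrophy pattern that is smooth and radially coherent.
Absolute biases on real data (e.g. the tendency of Jacobian integration
to underestimate change when partial-volume voxels are included in the
ROI) are therefore out of reach; what the phantom study does establish
is that each measure tracks a known truth within stated tolerances and
that the *variance ordering* between the measures — the package's central
claim — emerges at phantom scale.

On 20 matched 64³ pairs with 2.0% true GM loss (the default replicate
study, also run by `scripts/acceptance.R`), fluid + Jacobian integration
recovers the mean rate within ±0.4 %/yr with replicate SD well below
that of segmentation-subtraction, which recovers the mean within
±1.0 %/yr. Two systematic effects are visible and documented rather than
hidden: the registration route carries a small positive bias (it
converges from above through the +0.05–0.15 pp range at the default
iteration cap), and the segmentation route reads low by ~0.4–0.8 pp
because the sinc-warped follow-up has smoother boundary voxels than the
baseline — segmentation volumes are interpolation-sensitive at the ~3%
level under double resampling, which is the same fragility that makes
the method noisy on real serial MRI.

## Segmentation

`segment_tissues()` fits a 3-component Gaussian mixture to brain-voxel
intensities by EM (tercile initialization, jittered seeded restarts on
degeneracy, component-to-tissue assignment by ascending mean so the
labelling is invariant to initialization order), followed by two sweeps
of 6-neighbour posterior averaging restricted to the brain mask. It
deliberately carries no anatomical atlas priors: it is self-contained,
deterministic given its seed, and sufficient for the phantom's
three-class intensity structure; it is not a drop-in for atlas-based
segmentation of real MRI. Noise-free delta-like intensity classes are
handled by clamping component SDs at a floor rather than failing, so the
noiseless phantom segments exactly.

## The BBSI window

The boundary band is `dilate(base ∩ repeat, 1) \ erode(base ∩ repeat,
1)` with a 6-connected structuring element. The intensity window is
placed inside the CSF–GM transition as `[CSF + 0.25·g, GM − 0.25·g]`
with `g` the CSF–GM mean-intensity gap averaged over the two time
points. The quarter-gap rule is a documented package choice (exposed as
`frac`): it keeps the window inside the transition zone and away from
the pure-tissue plateaus, which is the property the integral needs; the
original window construction lives in prior work and is not reproduced
verbatim.

## Trial statistics

`sample_size_per_arm()` implements the standard two-arm formula with σ
taken from the patient group and the treated mean given by
`treatment_mean()`: a fraction `e` of the way from the patient rate
towards zero (no aging adjustment) or towards the control rate (aging
adjustment — the convention in which a perfect treatment restores normal
aging, not immortality). With the conventional rounded quantiles
(u = 1.28, v = 1.96; `paper_rounding = TRUE`) and ceiling rounding, the
1-year group summaries shipped in
`inst/extdata/cohort_summary.csv` reproduce the published per-arm sizes
120 / 202 / 110 / 111 / 196 exactly; recomputing the remaining rows from
their two-decimal printed means and SDs lands within a few subjects of
the printed values, and three aging-adjusted rows (printed 2081, 485 and
2047) differ by 12, 4 and 4 — with denominators of the form
(0.2·(μ₁−μ₂))² ≈ 0.07, a half-unit-in-last-place rounding of the printed
means moves n by more than 10, so exact agreement from printed inputs is
arithmetically impossible there. `rescale_design()` follows the
published extrapolation convention of scaling the *rounded* table entry
by the squared effect-size ratio (202 → 130 at a 25% effect;
`from = "raw"` rescales the unrounded value instead), and
`power_multiplier()` reproduces the 0.747 factor for 90% → 80% power.

`pitman_sd_ratio()` tests equality of paired variances through the
correlation of sums and differences, with the CI obtained by numerically
inverting the t bound on the rescaled pair — Monte-Carlo coverage at the
cohort's own moments sits inside [92%, 98%] at nominal 95%.
`bootstrap_ratio_ci()` resamples subjects within group, recomputes both
methods' sample sizes per replicate, and reads a BCa interval from the
order statistics; replicates where the treated and placebo means
coincide give infinite sample sizes and are retained (rank-based BCa
handles them, mirroring published intervals with open upper bounds).
`adjusted_group_difference()` is ordinary least squares of rate on group
with age and gender covariates.

## Degenerate inputs and tie-breaks

* Identical image pairs: the NCC body force is identically zero, so the
  fluid loop exits on its first mean-force evaluation; the BBSI is
  exactly zero; segmentation of identical inputs is identical, so
  subtraction is zero.
* `binarize_gm()` uses an inclusive threshold (`p ≥ 0.5`), so a uniform
  0.5 map is all-GM.
* Degenerate intensity regression (identical tissue means) falls back to
  the identity map with a warning; zero-variance images inside the mask
  are an error for the body force.
* Empty erosions warn rather than fail; empty ROIs and empty boundary
  bands are errors.
* All randomness (phantom noise, EM restarts, cohort draws, bootstrap)
  flows through explicit integer seeds; identical seeds give
  bit-identical outputs.

## Problem sizes used by the shipped studies

The replicate studies run at 64³ / 2 mm with 20 pairs (recovery and
variance ordering), 10 pairs (BBSI parenchymal loss), 2000 Monte-Carlo
replicates (Pitman coverage) and 1000–10000 bootstrap replicates; these
sizes were chosen so the full validation suite runs on a single CPU in
well under half an hour while keeping Monte-Carlo standard errors small
against every tolerance tested.

## Known limitations

* The affine stage optimizes NCC with Nelder-Mead over a 3-level
  pyramid; it is deterministic but not guaranteed globally optimal for
  initial misalignments far beyond its pyramid capture range (tens of
  mm).
* The fluid stage runs at a single resolution (the affine stage handles
  coarse alignment) and its greedy NCC flow, like all
  intensity-driven registration, inherits a small systematic bias from
  the interplay of interpolation models; on phantoms this is +0.05–0.15
  pp at 2% true loss.
* The segmenter has no atlas priors and no explicit partial-volume
  class; its 0.5-threshold GM volumes carry an interpolation-dependent
  offset that cancels only partially in subtraction.
* `simulate_cohort()` draws Gaussian rates; heavy-tailed outliers of the
  kind segmentation produced on real data (which dominate some published
  sample-size rows) are not modelled.
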