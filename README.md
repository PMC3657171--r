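# gmatrophy

Gray-matter (GM) atrophy rates from serial T1-weighted MRI, and the
clinical-trial statistics built on them.

In Alzheimer's disease the cortex loses volume at roughly 2% per year,
against ~0.5%/yr in healthy aging, which makes the GM atrophy *rate* a
candidate endpoint for disease-modifying trials. How the rate is
measured decides how large the trial must be: with the standard two-arm
formula

    n per arm = (u + v)^2 * 2 sigma^2 / (mu1 - mu2)^2

(u, v the normal quantiles for power and significance; mu1, mu2 the
placebo and treated mean rates; sigma the patient-group SD), the sample
size scales directly with the measurement variance. This package
implements three measurement techniques and the statistics layer that
turns their group summaries into per-arm sample sizes:

* **Segmentation + subtraction** — Gaussian-mixture tissue segmentation
  (`segment_tissues()`), GM mask at probability >= 0.5
  (`binarize_gm()`), volume difference (`seg_subtract()`).
* **Fluid registration + Jacobian integration** — viscous-fluid
  nonlinear registration of the repeat image to baseline
  (`fluid_register()`), then the integral of `1 - det J` over the
  baseline GM mask (`jacobian_integrate()`); one consistent deformation
  replaces two independent segmentations, cutting variance.
* **Brain boundary shift integral** — intensity-window-scaled integral
  of the aligned pair's difference over a one-voxel band at the
  parenchymal boundary (`bbsi_window()`, `bbsi()`).

Around these sit 12-dof affine registration, tissue-based intensity
normalisation, dilated-brain cropping, NIfTI-1 I/O, a three-tissue
digital phantom with *analytically known* atrophy for validation
(`make_phantom()`, `apply_known_atrophy()`), cohort simulation, and the
trial statistics: sample sizes with and without an aging adjustment
(`sample_size_per_arm()`), effect/power rescaling (`rescale_design()`),
Pitman's test for paired variances (`pitman_sd_ratio()`), BCa bootstrap
CIs for sample-size ratios (`bootstrap_ratio_ci()`), and
covariate-adjusted group differences (`adjusted_group_difference()`).

## Worked example

Sample sizes from published-style group summaries (AD mean 2.01 %/yr,
SD 0.96, n = 37; controls 0.46 %/yr):

```r
library(gmatrophy)
jac <- group_summary("AD", 37, 2.01, 0.96)
ctl <- group_summary("control", 19, 0.46, 0.27)
sample_size_per_arm(jac, design = trial_design())
#> <sample_size_result> 120 per arm (raw 119.732); mu1 2.01, mu2 1.608, sigma 0.96
sample_size_per_arm(jac, ctl, trial_design(aging = TRUE))
#> <sample_size_result> 202 per arm (raw 201.344); mu1 2.01, mu2 1.7, sigma 0.96, aging-adjusted
```

The first call assumes a fully effective treatment stops atrophy
entirely (mu2 = 0.8 * 2.01 at a 20% effect); the second, more
conservative, assumes it can at best restore the control rate, shrinking
the detectable difference to 0.2 * (2.01 - 0.46) = 0.31 %/yr and
raising the requirement from 120 to 202 subjects per arm.

End-to-end on a synthetic pair with known truth — a 64-cubed phantom
whose follow-up carries an analytically known 2.0% GM loss:

```r
ph <- make_phantom(phantom_spec(seed = 42))
fu <- apply_known_atrophy(ph$image, ph$truth, 0.02, seed = 43, mode = "gm")
run_pair(ph$image, fu$image, ph$brain, ph$brain,
         interval_days = 365.25, skip_affine = TRUE, seed = 42)
#> <pair_result>
#> <atrophy_result> seg_subtract: 4.152 mL of 279.26 mL (1.487%) over 365.25 d = 1.487 %/yr
#> <atrophy_result> jacobian_gm: 5.9257 mL of 279.26 mL (2.122%) over 365.25 d = 2.122 %/yr
#> <atrophy_result> bbsi: 3.5811 mL of 429.51 mL (0.8338%) over 365.25 d = 0.8338 %/yr
```

The registration-based measure lands on the known 2% loss (2.12 %/yr
over the segmented GM); segmentation-subtraction is noisier and here
under-reads (1.49 %/yr), illustrating exactly the variance contrast the
sample-size comparison quantifies; the BBSI row measures whole-parenchyma
change (true parenchymal loss for this pair is 1.24%), on a different
denominator. The methods vignette
(`vignettes/atrophy-measurement.Rmd`) documents the models, the phantom,
all tunable parameters and the known biases.

A thin command-line wrapper over the same functions is included at
`inst/cli/gmatrophy.R` (subcommands `phantom`, `run`, `samplesize`).

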