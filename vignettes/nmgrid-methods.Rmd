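---
title: "Methods: grid-section NM-MRI analysis and the synthetic-specimen generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-section NM-MRI analysis and the synthetic-specimen generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmgrid)
```

## Scope

`nmgrid` analyzes matched imaging and chemistry from grid-dissected ex vivo
midbrain slices: a neuromelanin-sensitive MRI (NM-MRI) volume per specimen,
and per-grid-section neuromelanin (NM, µg per mg wet tissue) and iron (Fe,
ng per mg wet tissue) concentrations. This vignette documents the models
and their assumptions, every tunable parameter that matters, the numerical
choices, what the synthetic-specimen generator does and does not emulate,
and the known limitations.

## The processing chain

### Low-signal threshold

The voxel intensity distribution of a specimen volume is assumed bimodal:
a left mode of voxels outside the specimen (immersion fluid, air, signal
dropout) and a right mode of tissue. `lowSignalThreshold()` fits a kernel
density estimate — Gaussian kernel, Silverman rule-of-thumb bandwidth, 512
grid points — and returns the global density minimum strictly between the
two highest modes. Ties break toward the lower intensity. A distribution
with fewer than two detected modes raises an explicit "unimodal histogram"
error; the function never silently returns an extremum. The bandwidth can
be overridden (`bandwidth` argument) when the rule of thumb oversmooths,
e.g. for very unbalanced mode masses.

### Flattening

Valid voxels are averaged over the slice dimension (`flattenVolume()`),
matching the physical situation: the dissected sections span the full slice
thickness, so the chemistry integrates over it and the image must too.
In-plane positions with no valid voxel in any slice are flagged invalid.

### Edge-artifact removal

Boundary voxels (valid voxels 4-adjacent to an invalid voxel or the image
edge) are dilated by `innerWidth = 2` voxels with a city-block (diamond)
structuring element and removed unconditionally. In the band extending
`bandWidth = 5` voxels further, voxels with CNR above `cnrCutoff = 0.40`
are removed — except in grid sections flagged as containing substantia
nigra (SN), where high CNR is signal, not artifact. Both depths are
measured from the original boundary by a two-pass city-block chamfer
transform; the test suite checks it against a brute-force distance oracle.

### Voxel outliers

Within each grid section, voxels whose Cook's distance in a constant-only
regression of CNR exceeds `cooksMultiplier / n = 4/n` are removed, with n
the voxel count of that section (not of the whole image). For the
intercept-only model the leverage is 1/n, so
`D_i = r_i^2 (1/n) / (s^2 (1 - 1/n)^2)`; this closed form is verified
against the leave-one-out definition in the tests. Sections with fewer
than 3 voxels pass unfiltered with a warning. Samples whose spread is at
floating-point noise level (relative range below 1e-8) are treated as
constant — otherwise the distances would be ratios of rounding errors.

### CNR normalization

CNR is the relative signal change against a reference region (RR) of crus
cerebri (CC) white matter, which has minimal NM content:
`CNR_v = (I_v - mode(I_RR)) / mode(I_RR)`. For continuous intensities the
mode is defined as the argmax of the same kernel density estimate used for
thresholding; a constant reference sample returns its value directly.

### Order of operations

The sequence is fixed as: 3D threshold → flatten → unconditional border
removal → provisional CNR (reference mode from the post-border image) →
conditional border band → Cook's filter per section → final CNR with the
final reference mode. The conditional band and the outlier filter need CNR
values, and CNR needs a cleaned reference region, so some ordering must be
chosen; computing the reference mode after the unconditional border
removal keeps rim artifacts out of the reference distribution, and the
final recomputation makes the reported CNR consistent with the final
voxel set. The reference mode is taken from the flattened image (the same
image on which the ROI is defined), not per slice.

### Grid registration and aggregation

Voxel centers are mapped into the grid frame by a rigid transform (origin,
rotation) and assigned by integer division by the section pitch (3.5 mm
converted to voxels); a center exactly on a boundary goes to the
lower-index section. Per usable section, `aggregateSections()` reports the
arithmetic mean CNR of valid voxels, and for SN sections the fraction of
voxels with CNR above `snCnrThreshold = 0.10` (an SN-content proxy).
Sections flagged invalid (lost to dissection/assay problems) are dropped;
sections with zero surviving voxels yield a missing mean with a warning.

## Statistical models

### Random-intercept mixed model

`fitMixedModel()` fits

$$\overline{CNR}_{gs} = \beta_0 + \beta_1 [\overline{NM}]_{gs}
 + \beta_2 [\overline{Fe}]_{gs} + \beta_3\, diagnosis_s + b_{0s}
 + \epsilon_{gs},$$

with Gaussian errors, one random intercept per specimen, and no random
slopes. The CNR response is expressed in percent, which puts the NM slope
on the scale of percent CNR per (µg NM/mg) — the scale on which such
estimates are conventionally reported — while section tables and group
differences keep CNR fractional, matching the defining formula. Fitting is
by maximum likelihood: with a single random intercept the covariance is
`sigma2e (I + lambda Z Z')`, so the likelihood profiles to a 1-D search
over `lambda = sigma2b/sigma2e`, solved by bounded scalar optimization
(tolerance 1e-10) with an explicit check of the `lambda = 0` boundary.
For a Gaussian response this coincides with the pseudo-likelihood
estimates of common mixed-model software; the tests cross-check
coefficients, standard errors and variance components against `lme4`.

Wald t statistics use `df = n - 4` (n sections minus the four fixed
effects); with the default cohort's 163 central-anterior sections this
gives df = 159. Two R² conventions for the fixed-effect predictions are
reported: the squared correlation with the observed response (primary) and
`1 - RSS/TSS`. The central-anterior subset is the primary analysis; the
posterior-midbrain subset is fitted separately because NM-MRI signal bears
no relation to NM content there.

### Bayesian group differences

`fitGroupDifference()` samples `metric = alpha + delta * diagnosis + b0s +
eps` per region and metric with weakly informative priors —
Normal(0, (10·sd(y))²) on location parameters, half-Normal(0, (5·sd(y))²)
on both scales — by Gibbs sampling (JAGS), four chains with randomized
seeds, 3000 iterations each with the first 1000 discarded, retaining 8000
posterior draws. A thinning interval of 10 compensates for the higher
autocorrelation of Gibbs sampling relative to Hamiltonian Monte Carlo on
the hierarchical scale parameter, so the retained draws carry comparable
information. Convergence is verified by split-chain R-hat on every
monitored parameter with the conventional 1.01 cutoff; non-converged fits
are flagged and warned about, never silently reported. Each region ×
metric pair is fitted separately; the significance marker in
`groupDifferenceTable()` indicates a 95% credible interval excluding zero.
No multiple-testing correction is applied.

## The synthetic-specimen generator

No raw specimen data are deposited, so the generator is the package's
test bed. It emulates, per specimen: a 3.5 mm dissection grid (7 voxels of
0.5 mm at the default image resolution, 5 slices of 0.6 mm), block-wise
region labels (SN, RN, CC, SC, PAG, unassigned, posterior) on a fixed
per-specimen layout with the posterior midbrain on the left and the
anterior (CC) side on the right, water well markers at the dish rim,
a bright two-voxel edge rim plus sparse deeper bright voxels (probability
0.02 at depths 3–7, amplitude `edge_amplitude = 0.6`), and random signal
dropout (`dropout_prob = 0.02` per voxel; dropout intensities fall below
the background mode). The default cohort is 7 AD + 4 PD specimens with 221
sections (13–36 per specimen): region section counts SN 60, RN 22, CC 35,
SC 17, PAG 18, plus 11 unassigned central-anterior and 56 posterior
sections and 2 sections flagged invalid, leaving 163 + 56 usable.

Concentrations are drawn per section from truncated-at-zero normal
distributions with region × group means and SDs taken from the published
cohort table; truncation is the physically sensible choice given that only
means and SDs are reported, and the tests compare sample moments against
the truncated distribution's closed-form moments. The 11 unassigned
central-anterior sections use CC-like parameters (white-matter-adjacent
tissue, the closest characterized option). The posterior midbrain is not
characterized region-wise; its defaults (NM-MRI 0.05 ± 0.05, NM
0.30 ± 0.10 µg/mg, Fe 40 ± 15 ng/mg) are a fixed choice of plausible
mixed-tissue values between the CC and midline gray-matter ranges, and its
CNR is drawn with no NM/Fe dependence, reproducing the absence of a
signal–concentration relationship there.

### The section-CNR model and its calibration

The published region × group CNR means cannot be reproduced by a single
linear model in NM, Fe and diagnosis — region contrast is only partly
explained by concentrations (fixed-effect R² ≈ 0.3), and the PAG and SC
group differences differ far more than their concentration differences
predict. The default generator (`cnrModel = "anchored"`) therefore anchors
each section's expected CNR at its region × group mean and adds
conditional within-region slopes on the concentration deviations:

$$CNR^{\%}_{gs} = 100\, m_{rg} + \gamma_1 (NM_{gs} - \mu^{NM}_{rg})
 + \gamma_2 (Fe_{gs} - \mu^{Fe}_{rg}) + b_{0s} + \epsilon_{gs}.$$

Because the anchors covary with the region-mean concentrations, the
marginal slopes recovered by the mixed model differ from the conditional
ones. The conditional slopes are therefore *calibrated*: γ was chosen
once, by simulation through the full pipeline (finite-difference response
surface over batches of 50–150 cohorts), so that the mean fitted marginal
slopes equal the published estimates (7.37 percent CNR per µg NM/mg and
0.050 per ng Fe/mg). The calibrated values, γ = (3.72, 0.0791), are
recorded in the default configuration. `residualSD = 1.0` percent CNR was
calibrated the same way so the fixed-effect R² averages ≈ 0.30 (its
ceiling under the anchored defaults is ≈ 0.31); `subjectInterceptSD` is
25% of `residualSD` — no between-specimen value is published, and keeping
it small relative to the residual keeps variance-component recovery
well-posed.

The alternative `cnrModel = "linear"` generates CNR directly from
`beta0 + beta1 NM + beta2 Fe + beta3 diagnosis + b0 + eps`. This mode is
the correctly-specified case: the fitted model coincides with the
generating model, so it carries the exact-recovery property (zero-noise
cohorts return the generating coefficients to 1e-6) and the
confidence-interval coverage property (95% CIs for the NM slope cover the
generating value at nominal rate). Under the anchored default those
textbook properties do not apply verbatim — the "generating slope" is a
calibrated marginal summary and the region-anchor structure inflates
model-based standard errors, so intervals over-cover it — which is why the
coverage test runs in linear mode.

### Rendering and the reference ROI

Voxel intensity is `tissue * (1 + CNR)` inside the specimen and
`background` outside (defaults 1000 and 100), a single multiplicative
mapping; magnetization-transfer physics is deliberately not modeled.
Ground-truth CNR is *post-normalization* by definition, so the reference
ROI — a traced 3 × 3 patch inside each CC section, standing in for the
manually traced white-matter ROI — renders at exactly the zero-CNR
intensity, and its voxels serve normalization only (they are excluded from
grid-section statistics). Anchoring the reference this way is what makes
the pipeline's CNR recovery exact on noise-free phantoms; normalizing
against the CC sections themselves would re-normalize data whose anchors
are already expressed relative to the reference, shifting every specimen
by its CC modal CNR.

### What passing tests do and do not show

The phantom exercises the pipeline's failure modes (bimodal thresholding,
boundary geometry, artifact and outlier rejection, registration,
mixed-model and MCMC inference) with known ground truth, so green tests
show the *implementation* is faithful. Real specimens differ in ways the
phantom does not emulate: continuous anatomy instead of block-constant
sections, within-section texture and partial-volume gradients, spatially
correlated noise, B0/B1 inhomogeneity, imperfect grid registration
requiring manual adjustment, and chemistry assay error. Passing tests
therefore do not certify performance on real data beyond the modeled
effects.

## Numerical choices

- Kernel density: Gaussian kernel, `bw.nrd0` bandwidth, 512-point grid;
  bandwidth overridable everywhere it is used.
- Mode of a continuous sample: KDE argmax; constant samples short-circuit
  to their value.
- Threshold tie-break: first (lowest-intensity) grid point of the minimal
  density between the two selected modes.
- Boundary detection 4-connectivity; dilation city-block; both are the
  conventions closest to the perimeter definition used by common image
  toolboxes.
- Profiled ML: `optimize` on `log(lambda)` in [-15, 10], tolerance 1e-10,
  with an explicit boundary comparison at `lambda = 0`; residual variance
  guarded away from exact zero so noise-free data remain fittable.
- Registration boundary rule: `ceiling(x) - 1` after rounding to 9
  decimals, so rotation float fuzz cannot flip assignments.
- Seeds: every stage derives its seed from the master seed by a fixed
  affine map modulo 2^31, so stages are independently reproducible.

## Problem sizes

Default test and acceptance runs use the cohort at its natural size
(11 specimens, 221 sections, ~34 × 70 × 5-voxel volumes): 50 replicate
cohorts for slope recovery, 25 for the Bayesian group differences and R²,
200 table-level simulations for interval coverage. These sizes keep the
Monte-Carlo error of the recovered means well inside the assessment
tolerances.

## Known limitations

- The Bayesian priors are weakly informative stand-ins; published
  estimates obtained with other software defaults (e.g. the SN Fe
  difference of 37.3 vs a raw mean difference near 34) may shrink
  slightly differently. The package reports both the posterior estimate
  and the raw group means.
- Partial grid sections are not modeled separately: the generator emits
  whole sections only, mirroring the convention of pooling partial
  sections with their adjacent full section (by the shared-edge rule) at
  dissection time.
- `df = n - 4` is a fixed convention, not a Satterthwaite approximation;
  with 11 specimens the specimen-level uncertainty in `beta3` is
  understated by it, which is one reason the diagnosis coefficient is not
  a reported quantity of interest.
- The isotropic-covariance reading of the mixed model is the simplest one:
  a single shared random-intercept variance and i.i.d. residuals.
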