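# nmgrid

Grid-section analysis of neuromelanin-sensitive MRI (NM-MRI) in ex vivo
midbrain specimens.

## The problem

Neuromelanin (NM) is the dark pigment of dopaminergic neurons in the
substantia nigra (SN); it binds iron (Fe), and both are disturbed in
Parkinson's disease (PD). NM-MRI is sensitive to regional NM (and NM-bound
Fe) content, but the relative contributions of NM and Fe to the signal can
only be disentangled by comparing the image against direct chemical
measurements of the same tissue. The experimental design this package
supports: post mortem midbrain slices (cohorts of Alzheimer's-disease (AD)
and PD donors) are scanned, then dissected along a 3.5 mm grid, and NM and
Fe concentrations are assayed in each grid section, giving matched imaging
and chemistry for every ~3.5 x 3.5 x 3 mm tissue cube.

`nmgrid` implements the full analysis chain for such data:

1. **Voxel cleaning** — a per-specimen low-signal threshold at the minimum
   between the two modes of the kernel-smoothed intensity histogram;
   averaging over slices to a 2D image; removal of the specimen boundary
   (perimeter dilated by 2 voxels) plus a conditional 5-voxel border band
   in which voxels with CNR > 40% are discarded (except in SN-containing
   sections); and per-section outlier rejection by Cook's distance > 4/n
   in a constant-only regression.
2. **CNR normalization** — per-voxel contrast-to-noise ratio against a
   reference region (RR) of crus cerebri (CC) white matter:
   `CNR_v = (I_v - mode(I_RR)) / mode(I_RR)`.
3. **Grid aggregation** — voxel-to-section registration (rigid transform +
   integer division by the grid pitch), per-section mean CNR, and for SN
   sections the fraction of voxels with CNR > 10%.
4. **Statistics** — the random-intercept linear mixed model

   CNR̄(g,s) = β0 + β1·[NM̄](g,s) + β2·[Fē](g,s) + β3·diagnosis(s) + b0(s) + ε(g,s)

   fitted by profiled maximum likelihood (CNR in percent; NM in µg/mg wet
   tissue; Fe in ng/mg), and a Bayesian hierarchical model of the AD→PD
   group difference per midbrain subregion and metric, sampled by MCMC
   with split-R-hat convergence checks.

Because no raw specimen data are publicly deposited, the package ships a
synthetic-specimen generator (`phantomConfig()`, `generateCohort()`)
producing NIfTI-like volumes and matched concentration tables whose ground
truth encodes the published region-wise distributions and fitted
relationships for the 11-specimen cohort (7 AD, 4 PD; 221 grid sections,
of which 163 central-anterior + 56 posterior are usable).

## Worked example

```r
library(nmgrid)

cfg <- phantomConfig(seed = 1)          # default 7 AD + 4 PD cohort
cohort <- generateCohort(cfg)           # volumes + ground truth
sections <- cohortSectionTable(cohort)  # clean, register, aggregate
nrow(sections)                          # 219 usable sections

fit <- fitMixedModel(sections, "central_anterior")
fit
```

```
Random-intercept mixed model (central_anterior sections, profiled ML)
  n = 163 sections, 11 specimens; df = 159
            estimate      se     ci_lo    ci_hi     t         p
(Intercept)  1.58500 1.27900 -0.940700  4.11000 1.239 2.170e-01
nm_conc      7.61500 3.07900  1.535000 13.70000 2.473 1.443e-02
fe_conc      0.04305 0.01956  0.004422  0.08168 2.201 2.917e-02
diagnosis    5.89200 1.02900  3.861000  7.92400 5.729 4.933e-08
  sigma_e = 6.301, sigma_b = 0 (percent CNR); R2 = 0.273 (corr), 0.273 (1-RSS/TSS)
```

The NM slope (7.62 percent CNR per µg NM/mg tissue in this single cohort;
mean ≈ 7.4 across replicate cohorts) and the Fe slope (0.043 percent CNR
per ng Fe/mg) estimate the independent contributions of NM and Fe to the
NM-MRI signal; both are significant at df = n − 4 = 159, and the fixed
effects explain about 30% of the section-level CNR variance (0.27 in this
cohort).

Per-region group differences:

```r
pag <- fitGroupDifference(sections, "PAG", "nm_mri", seed = 1)
pag
```

```
Bayesian group difference (PD - AD), PAG / nm_mri: 0.2201 [0.2037, 0.2365]
  8000 draws, max split-R-hat 1.0011
```

PD specimens show ~0.22 higher NM-MRI CNR in the periaqueductal gray than
AD specimens, with a 95% credible interval excluding zero.

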