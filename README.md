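# glymalps

Glymphatic-function analysis from diffusion MRI, amyloid-PET centiloid
quantification, and the biomarker statistics that connect them — built
for imaging methodologists who want the full DTI-ALPS analysis chain as
tested, reusable R functions, exercised end to end on synthetic data
with known ground truth.

## The science in brief

**DTI-ALPS.** At the level of the lateral-ventricle body, perivascular
spaces run along the x (left–right) axis while projection fibres run
along z and association fibres along y. Diffusivity along x in those two
fibre areas is perpendicular to the dominant fibres and indexes
perivascular (glymphatic) water movement:

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

where the D's are ROI-mean *frame-diagonal* tensor elements (not
eigenvalues) from a per-shell log-linear WLS tensor fit. An index near 1
means minimal perivascular diffusion. Hemispheric indexes are computed
first, then averaged per subject; shells (b = 1000 and 2000 s/mm²) are
fitted and reported separately.

**Amyloid PET.** `SUV = kBq/mL / (MBq dose / kg weight)` voxelwise, SUVR
against the cerebellar mean, and the centiloid transform
`CL = 100·(SUVR − SUVR_yc)/(SUVR_ad100 − SUVR_yc)` with configurable
anchors.

**Statistics.** VSRAD atrophy Z-score `(control mean − individual)/SD`;
0–100 normalization of ALPS, MMSE and VSRAD onto the centiloid-like
scale; one-way ANOVA with Fisher's LSD; Pearson regression with
confidence bands.

**Simulators.** Three-zone tensor phantoms with a perivascular gain
knob (and an analytic ALPS oracle), Rician-noise multi-shell DWI, PET
SUVR maps that round-trip their centiloid target exactly, and CN/AD
biomarker cohorts (27 + 56 by default) whose correlation structure is
configurable and whose analytic moments are exposed for recovery
testing. See `vignette("glymphatic-alps-methods")` for the model and
all design choices.

## Worked example

Simulate a CN-like subject's DWI, fit tensors per shell, and compute the
ALPS index:

```r
library(glymalps)

ph <- make_tensor_phantom(phantom_spec(pv_gain = 1e-4))
ph
#> <tensor_phantom> 40x40x18 grid, perivascular gain 0.0001 mm^2/s, analytic ALPS 1.4400

scheme <- make_gradient_scheme(n_dirs = 30, bvalues = c(1000, 2000))
dwi <- simulate_dwi(ph$field, scheme, snr = 30, seed = 7)
res <- compute_alps(dwi, scheme, ph$mask)
res[, c("b", "alps_L", "alps_R", "alps")]
#>      b alps_L alps_R  alps
#> 1 1000  1.435  1.441 1.438
#> 2 2000  1.426  1.435 1.430
```

The fitted subject index (1.438 at b = 1000) recovers the phantom's
analytic value 1.44 to 0.2% despite SNR-30 Rician noise. A simulated
cohort then reproduces the configured biomarker structure:

```r
coh <- simulate_cohort(cohort_spec(), seed = 7)
pearson_regression(coh$centiloid, coh$ALPS_b1000)
#> Pearson regression (n = 83): y = 1.414 + -0.001386 x, r = -0.570, p = 1.85e-08

group_compare(coh, "ALPS_b1000")
#> Group comparison of ALPS_b1000
#>  group  n     mean         sd
#>     CN 27 1.398972 0.09054909
#>     AD 56 1.318600 0.10285800
#> ANOVA F(1, 81) = 11.99, p = 0.000858
```

ALPS declines with amyloid burden (negative slope, |r| ≈ 0.6 in this
draw) and separates the groups; one cohort is one noisy draw, so
per-seed slopes and r scatter around the configured −0.0018 / 0.65.
PET quantification round-trips its target exactly:

```r
anchors <- centiloid_anchors()
suvr <- simulate_pet_suvr(ph$mask, 78.5, anchors)
centiloid(global_cortical_suvr(suvr, ph$mask), anchors)
#> [1] 78.5
```

## The analysis workflow

Numbered drivers under `analysis/` run the study sequence and write
tables (and figures, with ggplot2) to `results/analysis/`:

```sh
Rscript analysis/01_simulate.R     # phantoms, DWI, gradient files, cohort
Rscript analysis/02_fit_alps.R     # tensor fits, ALPS per shell vs analytic
Rscript analysis/03_pet_quant.R    # SUVR simulation -> SUV/SUVR/centiloid
Rscript analysis/04_cohort_stats.R # group summary, regressions, normalized slopes
```

`run_pipeline()` performs the same stages programmatically from a YAML
scenario (see `inst/extdata/default_scenario.yaml`) and writes a
manifest of output hashes; identical seed and config reproduce identical
hashes.

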