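---
title: "Methods: the DTI-ALPS glymphatic index, amyloid centiloid and biomarker statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS glymphatic index, amyloid centiloid and biomarker statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymalps)
```

# What this package computes

The glymphatic system drains interstitial waste — including β-amyloid —
through perivascular spaces. The DTI-ALPS method estimates its activity
from diffusion MRI without contrast agents, exploiting a geometric
accident at the level of the lateral-ventricle body: there the
perivascular spaces run along the left–right (x) axis, while projection
fibres run inferior–superior (z) and association fibres
anterior–posterior (y). Water diffusivity measured *along x* inside the
projection and association areas is therefore perpendicular to the
dominant fibres and reflects perivascular water movement, while the
diffusivities perpendicular to both the fibres and the perivascular
direction (y in the projection area, z in the association area) provide
the reference:

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx,proj},\, D_{xx,assoc})}
                      {\mathrm{mean}(D_{yy,proj},\, D_{zz,assoc})}.$$

An index near 1 means minimal perivascular diffusion; it increases with
perivascular diffusivity. The subcortical area is extracted for
completeness but never enters the index: its fibres run parallel to the
perivascular spaces, so its x diffusivity cannot isolate perivascular
water.

Around this core the package implements the full biomarker analysis it
belongs to: amyloid-PET quantification (SUV → SUVR against a cerebellar
reference → centiloid), the VSRAD atrophy Z-score, a 0–100 normalization
placing DTI-ALPS, MMSE and VSRAD on the centiloid-like scale, and the
group comparisons (one-way ANOVA with Fisher's LSD, chi-square for sex
ratios) and Pearson regressions that relate the biomarkers. Because no
patient data are distributable, the package also ships simulators —
tensor phantoms, Rician-noise DWI, SUVR maps, CN/AD cohorts — that
provide exact ground truth for every step.

# The imaging chain

## Coordinate conventions

The index is defined on diffusivities along *fixed anatomical axes*, so
axis semantics are load-bearing. Every volume is brought to canonical
RAS orientation at load time (x: left→right, y: posterior→anterior, z:
inferior→superior), spacing is taken from the affine, and
`axis_diffusivities()` returns the tensor's *frame diagonal* — never
eigenvalues. For any tensor with off-diagonal coupling the two differ,
and the test suite checks this distinction explicitly. Voxel indices in
ROI JSON files are 0-based; inside R the usual 1-based linear indices
are used.

## Tensor fitting

The fit solves $\log S = \log S_0 - b\, g^\top D g$ per voxel:
ordinary least squares on the log signal followed by one reweighting
pass with weights equal to the squared predicted signal (log-linear
WLS). This estimator is standard, deterministic, and exact on noiseless
data — the suite requires recovery of random SPD tensors to better than
1e-8 relative error from a 30-direction protocol. Numerical guards:

* signals are floored at $10^{-6} \hat S_0$ before the log, so noisy
  background voxels cannot produce $-\infty$;
* negative fitted diagonal diffusivities are clamped to 0 and the voxel
  flagged (diffusivities are physical);
* a voxel whose weighted normal equations are singular is marked invalid
  rather than aborting the volume;
* shells are fitted separately (all b0 frames + one shell), matching the
  two reported ALPS variants (b = 1000 and b = 2000 s/mm²), with frames
  assigned to a shell within ±50 s/mm² to absorb scanner jitter. One
  shared b0 frame is assumed.

## ALPS extraction

ROI means are arithmetic means over labelled voxels, excluding
invalid-fit voxels; an ROI left empty after masking is an error, not a
silent NaN. Hemispheric indexes are computed first and then averaged per
subject. The alternative — pooling ROI means across hemispheres and
taking one ratio — is *not* equivalent (mean of ratios ≠ ratio of
means); the per-hemisphere order matches the description of indexes
being averaged per participant, and a unit test pins the behaviour.

ROIs may be supplied as label volumes or built from JSON centre/shape
specifications; no automatic (atlas- or tractography-based) placement is
attempted, since the emulated study placed ROIs manually and the exact
size/placement is unstated. Consequences of that gap are structural:
phantom results validate the computation, not any particular clinical
ROI choice.

## PET quantification

`SUV = concentration [kBq/mL] / (dose [MBq] / weight [kg])` voxelwise;
SUVR divides by the cerebellar ROI mean (output reference mean is 1 by
construction); centiloid is the affine map sending a young-control
anchor SUVR to 0 and a typical-AD anchor to 100, open-ended outside that
range. The anchors are *calibration inputs*, not constants — they depend
on tracer, VOIs and software — so they live in configuration
(defaults `suvr_yc = 1.009`, `suvr_ad100 = 2.076`, standard PiB
global-cortical values). Decay correction, frame averaging (the 50–70
min window) and reconstruction are assumed done on-scanner; the module
consumes one static activity volume. Per-subject centiloid values from
any specific clinical software are not reproducible here (their internal
VOIs and anchors are unpublished); what the package implements and tests
is the transform's algebra and the simulate→quantify round trip, which
is exact to 1e-9.

# The simulators

## Tensor phantom

`phantom_spec()` places three bands per hemisphere (projection,
association, subcortical) at a ventricle-body slab on a 40×40×18 grid of
1.9×1.9×3.0 mm voxels, plus a cerebellum block and a cortical band for
PET, all disjoint by construction and validated non-empty. Default zone
diffusivities (mm²/s):

| zone | Dxx | Dyy | Dzz | dominance |
|---|---|---|---|---|
| projection | 0.80e-3 + g | 0.625e-3 | 1.60e-3 | z |
| association | 0.80e-3 + g | 1.60e-3 | 0.625e-3 | y |
| subcortical | 1.60e-3 | 0.70e-3 | 0.70e-3 | x |
| background / cerebellum / cortex | 0.80e-3 | 0.80e-3 | 0.80e-3 | — |

The perivascular gain `g` (additive to Dxx in the projection and
association zones) is the single disease knob. The analytic index is
`(0.8e-3 + g)/0.625e-3`: `g = 1e-4` gives a CN-like 1.44, `g = 6e-6` an
AD-like 1.29, and `g = 0` a floor of 1.28. Magnitudes sit in the
physiological white-matter range (axial diffusivity ≈ 1.6e-3,
radial ≈ 0.6e-3 mm²/s). `make_tensor_phantom()` returns the analytic
ALPS value, which serves as the oracle for the fitted pipeline.

## DWI synthesis

The forward model is the monoexponential tensor signal with directions
from a deterministic spherical Fibonacci lattice (30 per shell, 1 b0, at
b = 1000 and 2000 s/mm², matching the emulated protocol). Noise is
single-coil Rician — the correct distribution for magnitude MR — applied
as the magnitude of the signal plus complex Gaussian noise with
σ = S0/SNR, SNR defined on the b0 signal (default 30, a typical brain
DWI figure). The closed-form Rician mean (`rician_mean()`, via scaled
Bessel functions) anchors the noise-level tests. Every stochastic
operation takes an explicit seed and touches no global RNG state.

What the phantom does **not** emulate: anatomy (no template brain),
partial-volume and CSF contamination, eddy/motion/distortion effects,
multi-coil noise statistics, or PET point-spread blur. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to every real-world artefact.

## Cohort generator

Cohorts of 27 CN + 56 AD subjects are generated with centiloid as the
exogenous stage variable (CN 0.4 ± 6.7, AD 78.5 ± 33.4), because the
analysis frames amyloid burden as the axis against which the other
biomarkers are staged. ALPS at each shell follows its configured linear
link (b = 1000: slope −0.0018, intercept 1.436, r = 0.65), with residual
SD chosen so the *all-subject* correlation matches r:

$$\sigma_{res} = |slope| \cdot SD_{mix}(centiloid) \cdot \sqrt{1/r^2 - 1},$$

where $SD_{mix}$ is the analytic two-group mixture SD (≈ 45.9). This is
the only reading consistent with the configured r: it also reproduces
the target within-group ALPS SDs (≈ 0.097 CN, ≈ 0.114 AD). MMSE and
VSRAD are then generated from ALPS(b = 1000) by inverting their links
with analogous residuals. Only r is specified for each pair, so this
residual construction is one consistent choice among several — it fixes
pairwise correlations but implies, rather than controls, the marginal
variances of MMSE and VSRAD.

Two consequences are worth stating plainly. First, inverting the MMSE
link puts the raw CN MMSE mean slightly above 30, so clipping to the
legal [0, 30] range is heavy (roughly half to two thirds of CN values);
the generator reports the clipped fraction as an attribute rather than
truncating silently, and the recovery tests use the exact
clipped-and-rounded normal expectation as their oracle. Second, the
link-based VSRAD necessarily has a small marginal SD (≈ 0.11) and does
not reproduce independently specified VSRAD group summaries; the
correlation structure, not the VSRAD marginal, is what the generator is
for. `cohort_moments()` exposes every analytic moment the generator
targets, and all defaults are recorded in the shipped
`extdata/cohort_defaults.yaml`.

# Statistics

`pearson_regression()` reports OLS slope/intercept, Pearson r, the
two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$, and pointwise 95%
confidence bands for the mean response (the conventional dashed-band
display; sidedness and band definition are conventional choices since
only "confidence intervals" is specified). The suite cross-checks it
against closed-form covariance arithmetic to 1e-12.

`group_compare()` is one-way ANOVA plus Fisher's LSD: pairwise t-tests
on the pooled ANOVA mean square with its residual degrees of freedom and
*no* multiplicity correction — that is what LSD is. For two groups the
ANOVA F equals the squared pooled t (verified numerically), and a fully
degenerate column (identical values everywhere) is reported as F = 0,
p = 1 rather than NaN. Sex ratios use an uncorrected Pearson chi-square.
The significance threshold default is 0.05.

The normalization equations are implemented exactly as printed:

* `nDTI-ALPS = (ALPS_MAX − ALPS)/(ALPS_MAX − 1) × 100`
* `nMMSE = (30 − MMSE)/30 × 100`
* `nVSRAD = (VSRAD − VSRAD_MIN)/VSRAD_MAX × 100`

with `MAX`/`MIN` over all subjects, and constants always reported
alongside values. The nVSRAD denominator is `VSRAD_MAX`, not the range —
as printed — even though the formula then reaches 100 only when
`VSRAD_MIN = 0`; `vsrad_denominator = "range"` switches to the range
form for users who consider the printed form a typo. All three maps are
affine, so correlation magnitudes against centiloid are preserved and
normalized slopes relate to raw slopes by known factors (e.g. the
nDTI-ALPS slope is the raw ALPS-on-centiloid slope times
−100/(ALPS_MAX − 1)); both identities are tested. Regressions of
MMSE/centiloid/VSRAD pairs treat ALPS as the response — the orientation
under which the configured intercept (1.436) sits at the CN ALPS level.

# Problem sizes and validation design

The validation suite is sized to run on one CPU in well under its
budgets while keeping Monte-Carlo error far below the tolerances it
asserts: 50 random SPD tensors for exactness; 20 noise seeds per
perivascular-gain level (3 levels) for the pipeline-versus-analytic ALPS
check at SNR 30, asserted within 5%; 200 cohorts for parameter recovery
(slope within 10%, |r| within 0.05, group means within 3 Monte-Carlo
SEs of the generator's analytic moments); 500 cohorts for the
group-separation power estimate, whose empirical rejection rate at
α = 1e-5 is validated against a noncentral-F oracle computed from the
generator's own moments (≈ 0.78 under the default design — the oracle,
not an aspiration, is the reference). `scripts/acceptance.R` recomputes
the same quantities end to end from a fresh seed.

# Known limitations

* ROI geometry is configurable but synthetic; no claim is made that
  phantom ALPS values transfer to any specific clinical ROI protocol.
* At b = 2000 with SNR 30 the lowest tensor signals approach the Rician
  noise floor, biasing diffusivities slightly low; the ratio structure
  of the index cancels much but not all of this, which is why accuracy
  assertions target the b = 1000 shell the method itself prefers.
* The cohort generator reproduces pairwise correlation structure, not
  joint distributions; MMSE clipping and the VSRAD marginal are implied,
  not controlled (see above).
* Registration, segmentation and VBM internals are out of scope: the
  VSRAD module implements the Z-score formula on provided ROI
  summaries only.
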