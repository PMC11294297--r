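---
title: "Kidney VOI propagation and dosimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kidney VOI propagation and dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renaldosim)
```

# The problem

During Lu-177-DOTATATE peptide receptor radionuclide therapy the kidneys are
the principal organ at risk, and their absorbed dose is estimated from serial
quantitative SPECT/CT: the whole kidney parenchyma (WKP — cortex plus
medulla, excluding the pelvis) is delineated on CT, the delineation is
overlaid on each SPECT, the mean activity concentration is read out at each
imaging time point, a time–activity model is fitted and integrated, and the
time-integrated activity concentration (TIAC) is converted to dose.

The co-infused renoprotective amino-acid solution transiently swells the
kidney parenchyma: relative to a pre-therapy baseline, kidney volumes are
larger by roughly +8.8% around 4 h and +10.1% around 24 h post
administration, relaxing to about +1.1% by 48 h and 7 days, while the spleen
— a control organ that does not react to the infusion — stays constant.
If a *single* CT delineation is propagated unchanged to every time point
(a common time-saving shortcut), this anatomical change turns into a
quantification bias: a small (late) VOI sits strictly inside the enlarged
early-time-point kidney, and because SPECT blurs activity outward
(partial-volume effect), an interior VOI always reads a *higher* mean
concentration than the full organ. The bias propagates through the kinetic
fit into the absorbed dose.

`renaldosim` implements this entire chain as a config-driven, testable
pipeline on synthetic phantoms, so the direction and mechanics of the bias
can be exercised and audited end to end. It is an *emulation* of the study
design: the original patient images do not exist in the package, and
cohort-level magnitudes printed by the pipeline describe the synthetic
cohort, not the clinical one.

# Data model and geometry

All spatial objects live on axis-aligned voxel grids with axis order
(z, y, x), physical units mm, 0-based indices, and the voxel-centre
convention (`voxel_grid`, `grid_geometry`). Two default geometries mirror
the acquisition:

* SPECT: 4.42 mm isotropic voxels (`default_spect_geometry()`);
* CT-like label grid: 1.105 mm in-plane — exactly one quarter of the SPECT
  pixel, so in-plane resampling nests 4:1 — and 5 mm slices
  (`default_ct_geometry()`).

A VOI is a mask bound to a grid; binary after delineation, fractional after
resampling. Volumes are `sum(mask) x voxel volume`.

## CT-to-SPECT resampling

`resample_voi()` assigns each target voxel the fraction of its physical
volume covered by the source mask. Because both grids are axis-aligned
boxes, that coverage is computed *exactly* as a separable product of
per-axis interval overlaps (a three-way tensor contraction with banded
overlap matrices). An earlier candidate — probe-point supersampling at
4 points per axis — was rejected because 4.42/4 = 1.105 mm makes the probe
lattice exactly commensurate with the CT grid, which aliased sphere volumes
by more than 1%; the box-overlap scheme is its infinite-supersampling limit
and conserves total mask volume to machine precision wherever the target
grid covers the source. Quantification uses fractional masks
(`binarize_threshold = "fractional"`); a 0.5 threshold is the default for
binary output.

## VOI propagation and alignment

`propagate_voi()` copies a mask to other time points without any geometric
change — this *is* the single-delineation shortcut under study, so the
identity is deliberate. `align_voi()` is the surrogate for the manual
repositioning of CT VOIs on each SPECT: an exhaustive integer-voxel
translation search (within a user bound) maximising the mask-weighted mean
image value, with ties broken by smaller shift magnitude, then
lexicographically in (z, y, x). How the clinical adjustment was constrained
is not documented, so translation-only is this package's explicit surrogate;
it is off by default in experiments and exposed as a flag.

# Synthetic phantoms

`make_phantom()` rasterises parametric organs (ellipsoids, or kidney-like
"beans": an ellipsoid with a spherical indentation) onto the CT grid. The
shape scale is solved so the voxelised volume matches the target within half
a CT voxel; internally the rasteriser sorts voxels by shape-normalised
radius and keeps exactly `round(target / voxel volume)` of them (bean shapes
first bisect the carving scale, then rank-select), so the tolerance holds by
construction, with exact radius ties broken by array order.

Per-tag volume multipliers carry the anatomy through time. The defaults
(`default_volume_multipliers()`) encode the observed baseline-relative
kidney biases — 1.0877 at D0, 1.1007 at D1, 1.0110 at D2 and D7 — and 1.0
everywhere for the spleen control. The generated cohort draws per-kidney
baseline volumes from a truncated normal (mean 130.6, SD 46.1, range
27.7–248.8 mL) and spleen volumes around 183.5 mL, matching the reported
cohort statistics.

## Kinetics truth and rendering

The generating time course is the same five-parameter tri-exponential used
for fitting (below). In the default `activity_primary` mode the model value
is the organ's *total activity*, and the concentration painted at a time
point is activity divided by that tag's organ volume — so transient swelling
dilutes concentration, the hypothesised physiological mechanism. A
`concentration_primary` mode exists for kinetics-only tests. Default truth
rates are b = 0.01, c = 0.05, d = 0.7 /h with amplitudes scaled to a peak
concentration of ~0.3 MBq/mL (plausible for 7.5 GBq administrations);
subjects vary these lognormally (15% CV). These are scenario defaults, not
measured values. The slowest generated rate stays above the Lu-177 physical
decay constant (log(2)/159.53 h = 4.34e-3 /h), as any physical washout must.

`render_spect()` paints concentrations on the CT label grid, downsamples to
the SPECT grid by the same exact volume-weighted scheme, convolves with an
isotropic Gaussian PSF (sigma = FWHM/2.3548; default FWHM 12 mm,
representative of a medium-energy collimator at the 208 keV Lu-177
photopeak), and optionally applies Poisson noise on calibrated counts. The
Gaussian chain is the declared surrogate for Monte-Carlo OSEM
reconstruction: it reproduces the partial-volume spill that drives the
studied bias, but models no attenuation, scatter, septal penetration,
reconstruction artefacts, or respiratory motion. Passing tests therefore
demonstrate the *mechanics* of VOI-propagation bias under ideal
reconstruction, not clinical image fidelity.

# The tri-exponential model and TIAC

The time–activity concentration model is

$$f(t) = A_1 e^{-b t} + A_2 e^{-c t} - (A_1 + A_2)\, e^{-d t},$$

anchored at `f(0) = 0` by construction (nothing is on board before
administration) and integrating in closed form to

$$\mathrm{TIAC} = A_1/b + A_2/c - (A_1+A_2)/d .$$

`tiac_numeric()` provides an independent adaptive-quadrature oracle
(log-spaced panels to `37/min(rate)` plus the analytic exponential tail);
closed form and quadrature agree to 1e-8 relative over randomised valid
parameters.

## Identifiability, and why the fit minimises TIAC

Each organ contributes four positive-time samples (≈4, 24, 48, 168 h) plus
the structural zero anchor — four equations against five parameters. The
set of *exact* fits is therefore generically a one-dimensional manifold
(occasionally with disconnected branches), and the TIAC genuinely varies
along it: for the worked example `A1=2, A2=1, b=0.01, c=0.05, d=0.5`
(TIAC 214.0), exact interpolants exist with slow rates from below 0.003 to
about 0.0105 /h and TIACs from 214 up to 267. "The" least-squares solution
does not determine the TIAC, and no tie-breaking rule on SSE alone can.

`fit_triexp()` therefore returns a well-defined functional of the data: the
**minimum TIAC over all admissible exact fits** (amplitudes non-negative,
rates in [1e-4, 10] /h, model non-negative on the observed span). This is
the most conservative time-integrated activity consistent with the data; it
is deterministic, scale-equivariant, and immune to the divergent-tail
degeneracy (slow rate towards zero at finite amplitude, which sends TIAC to
infinity at negligible SSE). Numerically: variable-projection grid search
seeds a full Levenberg-Marquardt solve onto the interpolation manifold (all
distinct branches found are kept), damped Newton continuation walks each
branch along the slow rate with adaptive steps, and a golden-section pass
refines the minimum. On noise-free data from the generator's own truth
distribution the selected TIAC sits at or just below the generating value —
median within ~0.05%, never more than ~1% below; the residual spread is the
intrinsic non-identifiability of four time points, not an optimiser
property: two different truths on the same manifold produce identical data,
so no estimator can recover both. Non-interpolable inputs (possible with
noise and the non-negativity constraints) fall back to the best constrained
least-squares solution, flagged `converged = FALSE`. An all-zero series
returns TIAC 0 with rates at bound midpoints rather than erroring, since
zero-activity organs are legitimate inputs. Fits are unweighted by default;
a weights hook exists.

# Partial-volume correction and dose

The recovery coefficient (RC) is defined as measured/true for a uniform
object quantified in its own VOI, so correction *divides* by RC.
`compute_rc()` computes the shape-specific RC by blurring a unit object
painted on the VOI mask and taking the mask-weighted mean — a Gaussian-PSF
surrogate for patient-specific Monte-Carlo recovery simulation. `fixed_rc()`
is the recommended fixed kidney value 0.85. Note that a VOI-*mean* RC
approaches 1 only like $1 - 3\sigma \cdot 0.399 / R$ for a sphere of radius
$R$: at 12 mm FWHM even a 2 L sphere has RC ≈ 0.92, and the package's
computed values agree with a 4x-finer-grid convolution oracle to well under
1%.

Absorbed dose uses local energy deposition:
$$D = \mathrm{TIAC} \cdot \mathrm{LED},$$
with the unit chain fixed in one place: Bq·h/mL × 3600 → decays/mL, ÷ 1.05
g/mL → decays/g, × 147.9 keV × 1.602176634e-16 J/keV × 1e3 g/kg → Gy
(`tiac_to_decays_per_mL()`, `absorbed_dose()`). A
`photon_self_dose_factor` (default 1.0) exposes the optional self-absorbed
photon multiplier without changing the default formula; whether the 147.9
keV already contains a photon contribution is not documented, so the
default reproduces the bare LED expression.

# Agreement statistics

`bland_altman()` works on relative differences in percent. The denominator
is the pair mean by default (standard for percentage Bland-Altman); a
`reference` mode gives baseline-relative differences, and the pipeline's
volume analysis uses it so that a configured multiplier `m` is recovered
exactly as bias `100(m-1)`. Limits of agreement are bias ± 1.96 SD with the
sample (n−1) SD; 1.96 is fixed.

`wilcoxon_paired()` drops zero differences, ranks absolute differences with
midranks, and computes the two-sided p exactly — full enumeration of all
2^n sign assignments — for up to 12 effective pairs, switching to a normal
approximation with tie correction (midranks make the variance
`sum(r^2)/4`) and a 0.5 continuity correction beyond. The test is
implemented in the package because exact enumeration with midranks under
zero-dropping is the contract here; `stats::wilcox.test` cross-checks it on
tie-free data in the test suite.

# The cohort experiment

`run_experiment()` ties everything together per subject: phantoms at
baseline and the four post-administration tags; SPECT renders at ~4, 24, 48,
168 h (optionally jittered inside the observed scheduling windows);
quantification under five VOI strategies (tag-matched *reference*, and
`single_D0/D1/D2/D7` propagated without geometric change); RC correction
per mode (fixed 0.85 vs per-VOI specific); tri-exponential fit; TIAC; dose.
Cohort level: per-tag volume Bland-Altman + Wilcoxon against baseline
(kidneys pooled left+right by default — 36 pairs at n = 18, the paired unit
being the kidney; a per-subject pooling mode exists because the clinical
report is ambiguous on this), a delineation-by-measurement concentration
bias matrix, and per-strategy dose agreement against the reference,
including the fixed-vs-specific RC cross-comparison.

Determinism: one configuration seed drives cohort sampling, acquisition
jitter and (when enabled) Poisson noise, with per-subject/tag derived
streams, so identically-seeded runs write byte-identical reports; the stage
log (which carries wall-clock timings) is deliberately not part of the
report.

Default problem sizes: 18 subjects, ~1.1M-voxel CT label grids, ~70k-voxel
SPECT grids, 16 phantom rasterisations and 4 renders per subject, 360
kinetic fits per full experiment — a few minutes on one core, chosen so a
full cohort remains comfortable on a laptop.

# Known limitations

* The Gaussian PSF surrogate has no attenuation, scatter or reconstruction
  modelling; absolute RC values (~0.78 for typical kidneys here) are
  scenario-specific, and the fixed-vs-specific dose comparison reflects
  this synthetic gap rather than any clinical one.
* Organ shapes are smooth parametric solids; real parenchyma delineations
  are irregular, so rasterisation-tolerance results do not bound manual
  delineation variability.
* The TIAC estimator is conservative by design; when comparing against
  other implementations, expect their (arbitrary) interpolant to sit at or
  above this package's TIAC on the same data.
* Only translation alignment is provided; deformable registration and
  motion correction are out of scope.
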