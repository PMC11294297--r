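# renaldosim

Kidney dosimetry for Lu-177-DOTATATE therapy is built on serial quantitative
SPECT/CT: the whole kidney parenchyma (WKP) is delineated on CT, overlaid on
each SPECT, the mean activity concentration is read at each time point, a
time-activity model is fitted and integrated, and the result is converted to
an absorbed dose. The renoprotective amino-acid co-infusion transiently
swells the parenchyma (~+9% at 4 h, ~+10% at 24 h versus baseline, back to
~+1% by day 2), so the popular shortcut of propagating a *single* CT
delineation to every time point quantifies an enlarged kidney with a too
small VOI — and, because finite SPECT resolution blurs activity outward, an
interior VOI always reads high. The bias propagates through the kinetic fit
into the dose.

`renaldosim` is a synthetic, config-driven re-implementation of that whole
analysis chain for medical physicists and methods developers: parametric
kidney/spleen phantoms with time-varying volumes, exact CT-to-SPECT VOI
resampling, Gaussian-PSF SPECT rendering, recovery-coefficient
partial-volume correction, a constrained five-parameter tri-exponential fit
with closed-form time-integrated activity concentration (TIAC),
local-energy-deposition dose, and Bland-Altman / paired-Wilcoxon agreement
analysis over an 18-subject cohort experiment. Real NIfTI volumes and VOI
masks are accepted by the quantification and kinetics stages.

## The model at the core

Activity concentration follows the five-parameter tri-exponential

    f(t) = A1 e^(-b t) + A2 e^(-c t) - (A1 + A2) e^(-d t),   f(0) = 0,

fitted to the four measured concentrations (~4, 24, 48, 168 h) plus the
administration-time zero anchor, and integrated in closed form:

    TIAC = A1/b + A2/c - (A1 + A2)/d        [Bq h/mL]

Because four samples cannot pin five parameters, the package returns the
*minimum TIAC over all admissible exact fits* — deterministic, conservative,
and immune to the divergent-tail degeneracy (see the methods vignette).
Dose assumes local energy deposition:

    D = TIAC x 3600 / 1.05 g/mL x 147.9 keV x 1.602e-16 J/keV x 1e3  [Gy],

with partial-volume correction dividing the measured concentration by a
recovery coefficient (fixed 0.85, or computed per VOI from the PSF).

## Worked example

```r
library(renaldosim)

# kinetics: the closed-form reference case and its fit
p <- triexp_params(2, 1, 0.01, 0.05, 0.5)
tiac_closed_form(p)
#> [1] 214
y <- triexp_value(p, c(4, 24, 48, 168))
fit_triexp(ta_series(c(4, 24, 48, 168), y))$tiac
#> [1] 213.9381

# dose unit chain: 1e11 decays/mL at kidney density and 147.9 keV/decay
absorbed_dose(1e11)
#> [1] 2.25678

# a small 2-subject cohort experiment, noise-free
res <- run_experiment(experiment_config(n_subjects = 2, seed = 11))
res
#> <experiment_result> 2 subjects, 5 strategies, RC modes: fixed/specific
#>
#> Volume change vs baseline:
#>  organ_class tag n_pairs bias_pct   sd_pct loa_low_pct loa_high_pct wilcoxon_p
#>       kidney  D0       4    8.768 0.002711       8.763        8.773      0.125
#>       kidney  D1       4   10.070 0.001409      10.067       10.072      0.125
#>       kidney  D2       4    1.100 0.002744       1.095        1.106      0.125
#>       kidney  D7       4    1.100 0.002744       1.095        1.106      0.125
#>       spleen  D0       2    0.000 0.000000       0.000        0.000         NA
#>       ...
#>
#> Dose agreement vs reference:
#>   strategy  rc_mode mean_dose_Gy bias_pct  sd_pct
#>  reference    fixed        1.768   0.0000 0.00000
#>  single_D0    fixed        1.728  -2.3205 0.14463
#>  single_D1    fixed        1.718  -2.8927 0.16607
#>  single_D2    fixed        1.786   0.9917 0.09788
#>  single_D7    fixed        1.786   0.9917 0.09788
#>  ...
```

Reading the output: the generated kidneys swell by the configured +8.77% /
+10.07% / +1.10% / +1.10% against baseline while the spleen control stays
flat (the rasterisation reproduces the configured anatomy to a fraction of
a CT voxel). Delineating once at D2/D7 — a small VOI applied to the swollen
early kidneys — overestimates early concentrations (here +3.1% at D0,
+3.6% at D1 in `res$conc_agreement`) and biases the dose *upward*
(+0.99%); delineating once at D0/D1 biases it downward. The reference
strategy agrees with itself exactly, by construction.

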