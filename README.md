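# vctgrowth

Measurement-error analysis for volumetric CT (vCT) follow-up of small
pulmonary nodules: how reproducibly can a nodule's volume be measured,
how does that error propagate into the exponential growth-rate constant
used for doubling-time malignancy calls, and how long must the interval
between two scans be so that measurement noise alone rarely mimics
malignant growth.

It is aimed at quantitative-imaging and biostatistics researchers who
work with longitudinal nodule volumetry — for deriving error models from
repeat scans of stable nodules, for decision-rule operating
characteristics, and for simulation studies.

## The model

Nodule growth is exponential, `V(t) = V(0)·exp(k·t)`, with doubling time
`DT = ln2/k`; doubling times of 30–400 days (`0.00173 < k < 0.0231`
day⁻¹) are read as positive for malignancy. Repeat scans of stable
nodules show a volume SD proportional to the mean volume,
`σ_V = a·V̄` (clinically, `a ≈ 0.057`). Propagating that error through
the two-scan estimator `k = ln(V₂/V₁)/Δt` gives

    σ_k = a·√2 / Δt,

independent of nodule volume. A stable nodule's estimated `k` is then
`N(0, σ_k²)`, so the false-positive rate of the doubling-time rule is
the normal mass inside the decision band, and the shortest interval
with FPR below a target (e.g. 5%) follows directly. Sensitivity is
bounded by the lognormal distribution of malignant growth rates
(log-mean ln 0.015, log-SD 0.83); at finite intervals that distribution
is blurred by convolution with the `N(0, σ_k²)` measurement kernel.

A synthetic-cohort generator (`simulate_cohort()`) reproduces the
statistical structure of repeat clinical vCT — 89 stable nodules of
3–1300 mm³ with 3–8 scans each, proportional Gaussian noise, and a
lognormal malignant arm — so the whole pipeline is testable without
patient data.

## Worked example

```r
library(vctgrowth)

# synthetic stable cohort emulating the clinical arm, and its error fit
cohort <- simulate_cohort(cohort_config(n_nodules = 89, seed = 1))
fit_proportional_sd(summarize_cohort(cohort))
#> Proportional volume-error fit (sigma_V = a*Vbar), 89 nodules
#>   a = 0.0529 +/- 0.0025,  r^2 = 0.573 (uncentered 0.839),  p = 1.31e-36

# decision band and operating characteristics at a = 0.057
malignant_window()
#> Decision window: DT 30-400 days  <=>  0.00173 < k < 0.02310 /day
stable_fpr(81, 0.057)          # 0.0408  — FPR at an 81-day interval
optimal_interval(0.057, 0.05)  # 77      — first integer day with FPR < 5%
tpr_pure()                     # 0.6940  — lognormal mass in the band
tpr_blurred(a = 0.057, delta_t = 81)  # 0.6884 — after measurement blurring

# empirical pairwise analysis of the same cohort
empirical_fpr(cohort)$fraction # 0.0090  (5 of 558 forward pairs)
```

The fitted slope (here 0.0529) is one cohort's draw around the
generating value 0.057; the FPR numbers say that at an 81-day interval
measurement noise pushes about 4% of truly stable nodules into the
malignant doubling-time band, while ~31% of malignant nodules fall
outside the band for reasons unrelated to measurement error.

A thin command-line wrapper is installed at `inst/scripts/vctgrowth`
(subcommands `simulate`, `fit-sd`, `rates`, `optimal-interval`,
`empirical-fpr`, `fit-lognormal`); it delegates to `run_cli()`.

## Documentation

The methods vignette (`vignettes/vct-growth-error.Rmd`) gives the full
account of the model, the numerical choices, the generator's
calibration, and its limitations.
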