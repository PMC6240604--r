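# ocorm

Hemoglobin mass and intravascular volumes by optimized carbon monoxide
rebreathing.

## What this package is for

The optimized CO-rebreathing method (oCORM) measures total circulating
hemoglobin mass (Hbmass): a subject rebreathes a small CO bolus through a
closed spirometer circuit for two minutes, and the rise of
carboxyhemoglobin (COHb) in capillary blood quantifies the hemoglobin it
labeled. From Hbmass the red cell, plasma and total blood volumes (RCV,
PV, BV) follow — quantities of direct interest in heart failure, where
anemia, pseudoanaemia and volume overload must be told apart.

The method's mass balance,

    Hbmass = K · MCO · 100 / (ΔCOHb% · 1.39)

(K: barometric pressure/temperature correction; MCO: CO volume actually
circulating; ΔCOHb%: COHb rise over baseline at the 6/8-min sampling
times; 1.39 ml/g: Hüfner's number), assumes the tracer has mixed fully
through the vascular system by the time of sampling. In patients with a
severely reduced left-ventricular ejection fraction (EF < 30%) mixing is
slower, the 6/8-min COHb readings are still elevated, and Hbmass is
systematically underestimated. This package is aimed at researchers and
clinicians applying oCORM in such populations. It provides:

* the deterministic oCORM calculations (K, CO mass balance, ΔCOHb,
  Hbmass, RCV/BV/PV with the 0.91 whole-body hematocrit correction, and
  the 2-min CO uptake fraction);
* normalization of COHb time courses to the 15-min value and a linear
  mixed model (orthogonal polynomial time trends × group, random subject
  intercepts) giving per-timepoint group contrasts and the
  time-by-group interaction test;
* Monte Carlo propagation of the mixing-related inflation of the 6/8-min
  COHb readings (+1.0% SE 0.7 at 6 min, +0.4% SE 0.6 at 8 min, 100 000
  repetitions) into the resulting Hbmass error;
* a seeded synthetic two-group cohort generator reproducing published
  group characteristics and kinetics offsets, so the entire pipeline is
  testable without patient data.

## Worked example

The package ships a three-subject session file (low, medium and high
hemoglobin mass; K and the circulating CO volume precomputed):

```r
library(ocorm)
res <- analyze_sessions(example_sessions())
res[, c("subject_id", "k_factor", "mco_ml", "delta_cohb", "hbmass_g")]
#>   subject_id k_factor mco_ml delta_cohb hbmass_g
#> 1         S1    0.934   32.3       5.05    429.8
#> 2         S2    0.923   42.5       4.30    656.3
#> 3         S3    0.931   82.9       4.50   1233.9
```

Subject 2, for instance: ΔCOHb = (5.30 + 5.10)/2 − 0.90 = 4.30 points,
so Hbmass = 0.923 · 42.5 · 100 / (4.30 · 1.39) ≈ 656 g.

How wrong would these measurements be if the subjects' ejection fraction
were severely reduced and the conventional 6/8-min sampling were kept?

```r
mc <- mc_hbmass_error(example_sessions(), error_factor_model(), seed = 42)
mc[, c("subject_id", "mean_diff_g", "q5_diff_g", "q95_diff_g", "cv_pct")]
#>   subject_id mean_diff_g q5_diff_g q95_diff_g cv_pct
#> 1         S1       -3.75     -7.77      0.328 -0.874
#> 2         S2       -5.53    -11.44      0.437 -0.843
#> 3         S3      -10.23    -21.08      0.787 -0.829
summarize_mc_error(mc)$average_cv_pct
#> [1] -0.85
```

`mean_diff_g` is the mean simulated-minus-measured Hbmass over 100 000
repetitions: the delayed-mixing inflation of the 6/8-min COHb readings
makes the conventional protocol underestimate Hbmass by about 4–10 g
here, i.e. a cohort-average systematic error of roughly −0.9% — real but
clinically small.

A complete exam with hematology panel yields the volumes too:

```r
analyze_session(
  rebreathing_session("P01", "EFsev", co_administered = 45, co_lost = 3.6,
                      pressure = 755, temperature = 19,
                      cohb_baseline = 1.1,
                      cohb_series = c(`6` = 5.6, `8` = 5.5)),
  panel = hematology_panel(hb_conc = 16.2, hct = 44.2),
  k_convention = "stpd")
#> <hbmass_result> subject P01 (EFsev)
#>   K 0.929, MCO 41.4 ml, dCOHb 4.45 pts
#>   Hbmass 622 g; RCV 1696, BV 4217, PV 2521 ml
```

Synthetic cohorts and the kinetics comparison:

```r
cohort <- simulate_cohort(cohort_config(n_cont = 200, n_efsev = 200), seed = 1)
norm <- normalize_cohb(sessions_to_long(cohort$sessions))
group_contrasts(norm)           # EFsev - CONT per timepoint, SE, p
fit_time_group_model(norm)      # + polynomial time-by-group interaction
plot_kinetics(norm)             # group mean +/- SE normalized curves
```

A command-line front end wrapping the same functions is installed at
`system.file("cli", "ocorm.R", package = "ocorm")` with subcommands
`simulate`, `compute`, `kinetics` and `mc-error`.

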