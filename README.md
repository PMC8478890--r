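# walkrisk

Health-risk thresholds and binary-logit risk modelling for PM2.5 exposure
on walking trips.

Pedestrians are fully exposed to street-level particulate pollution, and
the body's earliest measurable response to fine particles (PM2.5) is a
rising heart rate.  `walkrisk` implements the complete analysis chain for
personal-monitoring walking campaigns — for exposure scientists,
transport-health researchers and biostatisticians working with paired
physiological and air-quality series:

1. **Interval aggregation.**  1 Hz heart-rate and 1-minute PM2.5/PM10
   series are tiled into fixed windows (60 s default) and heart rate is
   expressed as the heart-rate change rate relative to a 10-minute
   resting baseline, *r*ᵢ = (*t*ᵢ − *t*)/*t* (HR%).
2. **Per-volunteer thresholds.**  For each volunteer an ROC curve of HR%
   against their subjective safe/risk judgements is swept on a 0.005 HR%
   grid; sensitivity *T* = Z_TP/(Z_TP+Z_FN) and false-positive rate
   *F* = Z_FP/(Z_FP+Z_TN) give the Youden index *T* − *F*, whose maximum
   (ties toward the upper-left) is the volunteer's HR% cutpoint.  Curves
   are gated on AUC > 0.9, and the cutpoint is mapped to a PM2.5
   threshold by averaging the concentrations observed at that HR%.
3. **Risk model.**  Intervals are classified safe/risk by the per-person
   cutpoints and a five-covariate binary logit,
   ln(p/(1−p)) = β₀ + β₁·PM2.5 + β₂·male + β₃·youth + β₄·BMI-healthy +
   β₅·HR%, is fitted by a Newton–Raphson maximum-likelihood routine
   implemented in the package, yielding Wald tests, odds ratios exp(βⱼ)
   and group dose-response curves.
4. **Synthetic cohort.**  A simulator generates cohorts, exposure
   trajectories, heart-rate responses and judgement labels with the
   statistical structure such campaigns assume (four demographic groups
   of 112/97/85/74, PM2.5 in 0–300 μg/m³ with strongly correlated PM10,
   group-specific linear/S-shaped heart-rate responses, latent
   per-volunteer thresholds), so the whole pipeline runs and is testable
   without field data.

## Worked example

```r
library(walkrisk)

cfg <- sim_config(group_sizes = c(male_youth = 20, female_youth = 20,
                                  male_middle_aged = 20,
                                  female_middle_aged = 20),
                  seed = 11)
run <- run_pipeline(config = cfg)
run
#> walkrisk pipeline run (simulate mode)
#>   volunteers: 80, intervals: 9600 (9600 classified, 5243 risk)
#>   reliable thresholds (AUC > 0.90): 78 / 80 (97.5%)
#>   logit: loglik -1146.74 in 10 iterations, converged: TRUE

subset(run$threshold_summary$group_means, margin != "bmi")
#>      margin       level  n mean_pm25_threshold mean_hr_threshold
#> 1    gender        male 40            129.5094         0.2926647
#> 2    gender      female 40            124.5238         0.2908236
#> 3 age_group       youth 40            144.1617         0.3502172
#> 4 age_group middle_aged 40            109.8716         0.2332711
```

78 of the 80 simulated volunteers have a reliable (AUC > 0.9) ROC curve;
their mean PM2.5 thresholds order as expected — males tolerate slightly
more than females, youth substantially more than the middle-aged
(≈144 vs ≈110 μg/m³), reflecting the latent thresholds the cohort was
simulated with.

The reference calibration of the risk model ships with the package:

```r
w <- wald_and_or(reference_coefficients())
data.frame(variable = w$variable, beta = w$beta,
           odds_ratio = round(w$exp_beta, 3))
#>      variable   beta odds_ratio
#> 1 (Intercept) -6.323      0.002
#> 2        pm25  0.056      1.058
#> 3        male -0.264      0.768
#> 4       youth -0.393      0.675
#> 5 bmi_healthy -0.327      0.721
#> 6      hr_pct  0.108      1.114
```

Each unit of PM2.5 multiplies the odds of the risk state by 1.058 (+5.8%),
each percentage point of HR% by 1.114; being male, young, or in the
healthy BMI band multiplies them by 0.768, 0.675 and 0.721 respectively.
Risk probabilities and group curves evaluate the logistic transform of
the linear predictor:

```r
predict_risk(reference_coefficients(),
             data.frame(pm25 = 150, male = 0, youth = 0,
                        bmi_healthy = 1, hr_pct = 35))
#> [1] 0.9960497   # female middle-aged, healthy BMI, PM2.5 150, HR% 35

curves <- risk_curves(hr_pct = 35)   # four gender-by-age curves, 0-300
```

A thin command-line front end over the same functions lives at
`inst/cli/walkrisk.R` (subcommands `simulate`, `run`, `validate`).

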