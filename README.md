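# ntriss

Trauma survival-probability modelling with three TRISS-variant equations,
for trauma epidemiologists and registry analysts who need to score
patients, re-derive coefficients on their own cohorts, and validate
models the way two-center derivation/validation studies do.

## The models

Each model estimates the probability of survival

```
Ps = 1 / (1 + exp(-b)),   b = b0 + b1*x1 + ... + bk*xk
```

with mechanism-specific (blunt / penetrating) coefficients:

| template | predictors |
|---|---|
| NTRISS-like | BMR, SBP, NISS, Age(≥55) |
| TRISS SpO2 | GCS, SBP, SpO2, ISS, Age(≥55) |
| NTRISS-like SpO2 | BMR, SBP, SpO2, NISS, Age(≥55) |

BMR (the GCS motor component) keeps intubated patients analysable; SpO2
replaces the unreliable respiratory rate; NISS (sum of the three worst
squared AIS grades, regardless of body region) corrects the ISS's
one-injury-per-region restriction. GCS/SBP/SpO2 enter as RTS-style
category codes 0–4, BMR raw 1–6, ISS/NISS raw 0–75; see
`vignette("trauma-survival-models")` for why and how to override the
bandings.

The package ships the twelve published coefficient sets from a São Paulo
university hospital (HCFMUSP) and a San Diego level 1 trauma center
(UCSDMC), digit-for-digit (`builtin_coefficients()`), plus:

* anatomical/physiological scoring: `iss()`, `niss()`, `rts()`,
  `code_physiology()`, `add_trauma_scores()`
* scoring: `score_records()` (mechanism-matched equations per record)
* re-derivation: `split_test_derivation()`, `equalizing_weight()`,
  `fit_logistic()` (weighted IRLS with separation flagging),
  `derive_all()`
* validation: `auc()`, `auc_ci()` and `delong_test()` (DeLong structural
  components), `sens_spec_at_optimum()` (Youden), `evaluate_matrix()`,
  `compare_cohorts()`, `autoplot()` methods
* a synthetic two-center registry generator with a known logistic truth:
  `generate_registry()`, `registry_config()`, `truth_report()`
* one-call orchestration: `run_full_study()`

## Worked example

```r
library(ntriss)
library(dplyr)

reg <- generate_registry(registry_config(seed = 42)) |>
  add_trauma_scores()

# score every record with the HCFMUSP NTRISS-like equations
scored <- score_records(reg, builtin_coefficients(),
                        origin = "HCFMUSP", template = "NTRISS_like")
scored |> select(patient_id, mechanism, bmr, sbp_code, niss, age55, ps) |> head(4)
#> # A tibble: 4 × 7
#>   patient_id mechanism     bmr sbp_code  niss age55     ps
#>   <chr>      <chr>       <int>    <int> <int> <int>  <dbl>
#> 1 H000001    blunt           6        2    50     1 0.0706
#> 2 H000002    blunt           4        4     1     0 0.988
#> 3 H000003    penetrating     3        4    10     1 0.923
#> 4 H000004    blunt           3        4    14     0 0.934
```

Record 1 (NISS 50, hypotensive, aged ≥55) gets a 7% survival
probability; record 2 (minor anatomy, intact physiology) 98.8%. Crossing
both centers' equations with both synthetic cohorts:

```r
evaluate_matrix(reg, builtin_coefficients()) |>
  filter(template == "NTRISS_like") |>
  select(origin, population, auc, ci_low, ci_high, sensitivity, specificity)
#> # A tibble: 4 × 7
#>   origin  population   auc ci_low ci_high sensitivity specificity
#>   <chr>   <chr>      <dbl>  <dbl>   <dbl>       <dbl>       <dbl>
#> 1 HCFMUSP HCFMUSP    0.878  0.860   0.896        76.7        85.4
#> 2 HCFMUSP UCSDMC     0.821  0.772   0.869        83.8        71.3
#> 3 UCSDMC  HCFMUSP    0.864  0.845   0.883        79.9        77.8
#> 4 UCSDMC  UCSDMC     0.840  0.795   0.885        78.3        76.6
```

Each row is one origin-population cell: the AUC with its DeLong 95% CI
and the Youden-optimal sensitivity/specificity (percent), survivors being
the positive class. `evaluate_matrix(..., iss_cutoff = 16)` splits every
cell into ISS < 16 / ≥ 16 severity strata, and
`run_full_study(run_config(seed = 1))` chains
simulate → split → derive → score → validate → compare in one
reproducible call.

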