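---
title: "Trauma survival probability with TRISS-variant models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trauma survival probability with TRISS-variant models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntriss)
library(dplyr)
```

## The problem

TRISS-style methodology estimates each trauma patient's probability of
survival, Ps, from physiology, anatomy and age, and is the workhorse of
trauma-care quality programmes: observed deaths are compared against the
deaths a reference model predicts. ntriss implements three variants of the
classic TRISS equation that replace hard-to-collect inputs with bedside
ones:

* **NTRISS-like** — best motor response (BMR, the motor component of the
  Glasgow Coma Scale), systolic blood pressure (SBP), the New Injury
  Severity Score (NISS) and an age indicator. Using BMR instead of the
  full GCS keeps intubated patients analysable; NISS corrects ISS's
  restriction to one injury per body region.
* **TRISS SpO2** — GCS, SBP, peripheral oxygen saturation (SpO2), ISS,
  age. SpO2 replaces the respiratory rate, which is frequently missing or
  distorted by pain and stress at primary assessment.
* **NTRISS-like SpO2** — BMR, SBP, SpO2, NISS, age.

All three share the logistic form

$$ P_s = \frac{1}{1 + e^{-b}}, \qquad
   b = b_0 + b_1 x_1 + \dots + b_k x_k, $$

with separate coefficient vectors per trauma mechanism (blunt /
penetrating) and per deriving cohort. The package ships the published
two-center sets — a São Paulo university hospital (HCFMUSP, a
middle-income setting) and a San Diego level 1 trauma center (UCSDMC, a
high-income setting) — twelve sets in all
(`builtin_coefficients()`), stored as exact decimal strings so they
survive any round trip digit-for-digit. One shipped value is anomalous
and deliberately left as published: the NTRISS-like SpO2 / HCFMUSP /
penetrating age coefficient is +10.7638537 while every other age
coefficient is negative. We reproduce rather than "correct" it; scoring
with that set will *raise* Ps for patients aged 55+.

## Predictor coding conventions

The source publication never states how GCS, SBP, SpO2 or BMR are coded
inside the equations, and the original authors' choice is unrecoverable.
The magnitudes of the published coefficients (e.g. SBP slopes of 0.8-1.6)
rule out raw mmHg inputs, so the package adopts — and documents as its
own convention — small-integer codings in the style of the Revised Trauma
Score:

| predictor | enters as | default coding |
|---|---|---|
| BMR | raw 1-6 | GCS motor component |
| GCS | code 0-4 | RTS bands: 13-15→4, 9-12→3, 6-8→2, 4-5→1, 3→0 |
| SBP | code 0-4 | RTS bands: >89→4, 76-89→3, 50-75→2, 1-49→1, 0→0 |
| SpO2 | code 0-4 | ≥95→4, 90-94→3, 80-89→2, 1-79→1, 0→0 |
| ISS / NISS | raw 0-75 | sums of squared AIS grades |
| Age | indicator | 0 if <55 years, 1 otherwise |

The SpO2 banding mirrors the RTS structure (there is no canonical RTS
band for saturation); every band table is replaceable per call via the
`bands` argument of `code_physiology()` / `add_trauma_scores()`, so users
who believe a different convention was used can swap it without touching
the models. The RTS itself (weights 0.9368, 0.7326, 0.2908 on coded GCS,
SBP, RR) is computed only for cohort description.

Anatomical scoring follows universal registry practice: ISS is the sum of
squares of the worst AIS grade in each of the three most severely injured
of six body regions, NISS the sum of squares of the three worst grades
regardless of region; both are 75 whenever any AIS-6 injury is present,
and missing third (or second) terms contribute zero. NISS ≥ ISS always.

```{r scoring-example}
x <- injury_table(c("head_neck", "head_neck", "chest"), c(4, 3, 2))
c(iss = iss(x), niss = niss(x))
```

## Scoring and validation

`score_records()` assembles each record's predictor vector and returns
`ps`. Records missing a required predictor are flagged (`scorable =
FALSE`) and counted, never silently dropped — mirroring the listwise
deletion implied by registry "no information" rows. With a coefficient
table, blunt and penetrating records automatically receive their
mechanism-matched equations.

Validation treats **survival as the positive class**, so informative
models have AUC > 0.5, matching the orientation of the published
performance tables. The package computes:

* `auc()` — Mann-Whitney AUC with ties counted one half;
* `delong_variance()` / `auc_ci()` — the nonparametric AUC variance from
  DeLong structural components (placement values), normal-approximation
  CIs clipped to [0, 1] (published tables likewise print upper bounds of
  exactly 1.000);
* `delong_test()` — the paired test for two correlated AUCs via the
  covariance of placement values;
* `sens_spec_at_optimum()` — the published tables report
  sensitivity/specificity without a threshold rule, so the package uses
  the Youden-optimal cut as its documented default. Candidate thresholds
  are −∞ plus midpoints between consecutive distinct scores (a record is
  called a survivor when `ps >= threshold`); ties in Youden's J break
  toward higher specificity. A degenerate all-tied score vector therefore
  returns (100, 0) from the single −∞ cut.

`evaluate_matrix()` crosses every equation origin with every test
population and template (12 cells; 24 when split at ISS 16), and
`compare_cohorts()` reproduces the descriptive two-center comparison
(Pearson chi-square without continuity correction for categories, one-way
ANOVA for continuous variables).

## Re-deriving coefficients

`split_test_derivation()` holds out `n_test` (default 300) records drawn
uniformly from the records complete for *all* models; the remainder forms
the derivation database, and test ids never enter any fit (asserted in
the pipeline). With the default cohort sizes this reproduces the
published derivation sizes 2116 and 7872, whose ratio is the
cohort-equalizing weight 3.72 (`equalizing_weight()`): each smaller-cohort
record carries that weight so both cohorts contribute equally *when
pooled*. A constant per-record weight rescales the likelihood uniformly,
so it cannot change separate per-center maximum-likelihood estimates;
the package implements the weight as described, and tests document this
no-op property explicitly.

`fit_logistic()` is a weighted iteratively-reweighted-least-squares
fitter (outcome 1 = survived; convergence when the largest coefficient
change drops below `tol = 1e-8`, at most `max_iter = 100` iterations).
Complete separation — runaway coefficients without convergence, or a
singular information matrix — is flagged (`separation = TRUE`) with the
last iterate returned, never silently "fixed"; penalised alternatives are
out of scope. Point estimates and standard errors agree with
`stats::glm` to numerical precision on every tested fit. `derive_all()`
repeats the fit per template × center × mechanism, skipping empty or
single-outcome strata with a warning, and emits the published-table
shape.

## The synthetic registry

No patient data are distributed, so `generate_registry()` builds
two-center cohorts with the published descriptive structure and — the
crucial part — a *known* logistic truth, making every downstream stage
testable against its generating model:

* demographics, mechanism mix, SBP/SpO2/RR (truncated normals on
  [0, 300], [0, 100], [0, 60]), age (truncated at 14, the study's
  inclusion floor) and GCS-band probabilities are taken per center from
  the published cohort table;
* the GCS total is uniform within its drawn band and the motor component
  follows a fixed feasible decomposition table (eye 1-4, verbal 1-5
  bound the motor value);
* injuries have uniform regions, `1 + Poisson` counts and categorical
  AIS-grade distributions calibrated once so the arms hit the published
  mean ISS contrast (13.7 severe vs 8.6 mild); AIS 6 is rare (0.1-0.2%);
* survival is Bernoulli(Ps) with Ps from the published NTRISS-like set of
  the record's center and mechanism applied to the record's own coded
  predictors (`registry_config(generating_template = )` to change);
  `truth_report()` writes the generating table in the standard JSON
  format for recovery comparisons;
* optional per-field missingness is applied last (defaults ~1% of GCS,
  0.08% of mechanism at the severe center, as in the published table),
  so it is observational and cannot influence outcomes.

Everything is reproducible byte-for-byte under one master seed, with
per-center child seeds derived deterministically.

### What the generator does and does not emulate

The generator matches *marginal* distributions and the severity/mortality
contrast between arms. It deliberately does **not** correlate physiology
with anatomy beyond what the outcome link induces: a hypotensive record
is no more likely to carry severe injuries than a normotensive one. This
has a consequence worth understanding. For a calibrated risk model,
discrimination grows with risk heterogeneity; in these simulations the
severe, heterogeneous arm therefore yields *higher* AUC (~0.83-0.87)
than the homogeneous mild arm, whereas the real two-center study observed
the opposite (0.91-0.98 on the mild cohort vs ~0.85 on the severe one).
In real registries deranged physiology, severe anatomy and death arrive
together, concentrating the mild cohort's few deaths in an easily ranked
tail. Passing tests on this generator consequently demonstrate correct
arithmetic, correct derivation and correct validation machinery — not
that the real-data case-mix findings re-emerge; the suite states that
expectation as an explicit (and currently failing) check rather than
weakening it, and this limitation is the reason.

## Numerical choices

* `survival_probability()` uses the stable logistic transform; |b| ≥ 700
  saturates to 0/1 without overflow, NaN/±Inf inputs are errors, missing
  propagates.
* AUC and placement values are computed from midranks, so tied scores
  need no special-casing; brute-force pair counting and direct
  structural-component computations back them in tests to 1e-10.
* Coefficients are carried as exact decimal strings next to their
  numeric values; files written by `write_coefficients()` re-read
  identically.
* IRLS clamps fitted probabilities to [1e-12, 1 - 1e-12] inside the
  likelihood only, to keep weights finite near separation.
* Degenerate evaluation cells (fewer than two records in either outcome
  class) are reported as `NA`, never fabricated.

## Problem sizes used by the test suite

The suite generates its fixtures at run time: unit tests use cohorts of
a few hundred records; the invariants use 20,000-record single-center
cohorts for moment checks and coefficient recovery (five seeds, every
coefficient within 3 SE of truth); the study-scale checks use the full
default sizes 2416 + 8172. The complete suite runs in well under a
minute, and `scripts/acceptance.R` in a few seconds.

## Known limitations

* The predictor codings are documented conventions, not the original
  authors' (unrecoverable) choice; absolute Ps values depend on them.
* Original TRISS (RTS + ISS with MTOS coefficients) is supported only
  through user-supplied coefficient files; no MTOS coefficients ship.
* AIS dictionary lookup (7-digit codes → region/severity) is out of
  scope; callers supply region and grade.
* The mild-arm/severe-arm AUC inversion discussed above.
* The severe arm's synthetic mortality (~15%) and the mild arm's (~1%)
  are implied by the published truth coefficients under the documented
  codings, not tuned to the published 17.4% / 2.5%.
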