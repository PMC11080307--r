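# parasurv

Parametric Weibull survival modelling for right-censored cohort data, with a
semiparametric Cox comparator, assumption diagnostics, and censoring-aware
accuracy comparison.

## The problem

Cox proportional-hazards (PH) regression is the default tool for
overall-survival analysis in oncology cohorts — for example endometrial
cancer studies combining clinical covariates (age at diagnosis, tumour
grade) with MRI radiomic texture features. But the Cox model leaves the
baseline hazard unspecified, so it can report only hazard ratios. The
Weibull regression model, with hazard

$$h(t \mid z) = \gamma \lambda t^{\gamma-1} e^{\beta' z},$$

is the one parametric family that is simultaneously a PH and an accelerated
failure time (AFT) model. A fitted coefficient $\beta_i$ therefore yields
both the hazard ratio $HR = e^{\beta_i}$ **and** the event time ratio

$$ETR = e^{-\beta_i/\gamma},$$

the multiplicative change in the time at which any fixed survival
percentile is reached — a quantity clinicians often find easier to read
than a hazard ratio ($ETR < 1$ means shorter survival). `parasurv`
implements this analysis end to end for biostatisticians and imaging
researchers:

* **`fit_weibull_aft()`** — censored maximum likelihood on the internal
  scale $(\log\gamma, \log\lambda, \beta)$ with analytic gradients, plus
  `hazard_ratio()`, `event_time_ratio()`, `percentile_time()`,
  `time_ratio()`, `predict_survival()` and the nonparametric-vs-parametric
  cumulative-hazard overlay `check_distribution()`.
* **`fit_cox()`** — the Cox comparator (via the survival package) with
  `ph_test()` (scaled Schoenfeld score test), `schoenfeld_residuals()` and
  `martingale_residuals()`.
* **`fit_univariate()` / `ks_statistic()` / `qq_pp_points()`** — is the
  marginal death-time distribution Weibull, log-normal or log-logistic?
* **`brier_curve()` / `auc_curve()` / `null_model_curve()` /
  `bootstrap_curves()`** — IPCW time-dependent AUC and Brier score with
  reverse-Kaplan-Meier censoring weights and bootstrap bands.
* **`cohort_spec()` / `generate_cohort()` / `split_cohort()`** — a seeded
  synthetic cohort generator emulating an endometrial-cancer-like study
  (411 training / 80 testing subjects, ≈23% deaths), so the whole pipeline
  is testable without clinical data.
* **`run_pipeline()`** — the orchestrated analysis producing a
  coefficient/HR/ETR table, diagnostics, distribution fits and metric
  curves, written as deterministic JSON/CSV artifacts. A thin command-line
  wrapper lives in `inst/scripts/parasurv`.

## Worked example

```r
library(parasurv)

spec   <- cohort_spec(n_subjects = 491, seed = 11)   # study-like defaults
cohort <- generate_cohort(spec)
parts  <- split_cohort(cohort, test_fraction = 80 / 491, seed = 11)
nrow(parts$train); nrow(parts$test)   # 411 and 80

report <- run_pipeline(pipeline_config(spec = spec, sim_seed = 11,
                                       boot_seed = 3))
report
```

```
Analysis report: n_train = 411 (101 events), n_test = 80 (13 events)
Weibull shape 0.9694, scale 3.209e-05 per day^shape

Effect estimates:
  predictor weibull_coef weibull_hr weibull_etr cph_coef cph_hr
1       age       0.6378     1.8923      0.5179   0.6220 1.8627
2    grade2       0.4793     1.6149      0.6099   0.4575 1.5801
3    grade3       2.3136    10.1110      0.0919   2.2707 9.6864
4     rad_1       0.4280     1.5341      0.6431   0.4189 1.5202
5     rad_2       0.0987     1.1037      0.9032   0.0948 1.0995
6     rad_3       0.1277     1.1362      0.8766   0.1228 1.1307

PH global test p = 0.004921 (km transform)
```

Reading the first row: a one-standard-deviation increase in age multiplies
the death hazard by 1.89 and shrinks the time to any fixed survival
percentile to 52% — the two readings of the same Weibull coefficient. The
Weibull and Cox coefficient columns agree closely because Weibull data are
proportional-hazards data; grade 3 carries the dominant effect, as in the
generative truth. (The global Schoenfeld p-value here is small by chance
for this seed; its type-I error is calibrated in the test suite.)

Closed-form work with published coefficients needs no data at all:

```r
ref <- reference_effects("training")   # published worked-example table
m <- weibull_aft_model(attr(ref, "gamma"), attr(ref, "lambda"),
                       setNames(ref$weibull_coef, ref$predictor))
hazard_ratio(m, "Age")$estimate       # 1.754177  (printed: 1.7541)
event_time_ratio(m, "Age")$estimate   # 0.5677814 (printed: 0.5678)
percentile_time(m, z = rep(0, 6), p = 0.95)  # 1776.6 days to 95% survival
```

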