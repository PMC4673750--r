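# adaptsig

Subgroup identification and testing for biomarker adaptive signature
designs in randomized two-arm trials.

Targeted therapies are expected to help only a marker-positive (`g+`)
subpopulation. An adaptive signature design develops a subgroup
classifier and tests the treatment effect in the classifier-selected
subgroup *within the same study*, which puts two statistical problems in
one place: building an accurate `g+`/`g-` classifier from
high-dimensional pre-treatment expression data, and testing treatment
effect in all patients and in the selected subgroup under a single
study-wise error budget. A classifier with imperfect operating
characteristics does real damage here — misclassified patients dilute
the subgroup contrast (in a typical strong-effect scenario a true odds
ratio of 16 attenuates to about 2 at sensitivity 0.991 / specificity
0.644) — so the package treats classifier evaluation as a first-class
output, not an afterthought.

## What is implemented

* **Marker screening.** Per-probe treatment x marker interaction models
  `h(y) = b0 + b2 t + b3 (z t)` — logit link for binary endpoints, Cox
  for survival — with two-sided Wald tests of the interaction `b3`. The
  genome-wide binary scan runs in compiled code (exact ML; the
  likelihood factorizes over arms). Binary screening keeps probes with
  `p <= alpha_screen` (default 0.001); survival screening keeps the
  top-K genes (default 5).
* **Three subgroup classifiers.** Diagonal linear discriminant analysis
  (`dlda()`, pooled per-feature variances, no matrix inversion); the
  adaptive-signature odds-ratio voting rule (`asd_rule()`: patient is
  `g+` when `b2 + b3 x > ln R` for at least `G` markers); and a Cox
  risk-score rule (`cox_score()`: `g+` when the predicted survival
  probability at a horizon meets a cutoff, default `S(5y) >= 0.5`).
* **Cross-validated assignment.** `cross_validated_assignment()`
  re-screens and re-fits within every training fold (10-fold or
  leave-one-out), so each patient is labelled by a model that never saw
  them; per-fold audits make the no-leakage property checkable.
* **Testing strategy.** `run_comparisons()` reports the five
  comparisons — treatment effect in all patients, in `g+`, in `g-`, and
  `g+` vs `g-` within each arm — with the study-wise alpha split
  `alpha1` (overall, one-sided 2%) + `alpha2` (subgroup, 3%);
  `summarize_power()` implements the overall-power accounting (overall
  rejections plus subgroup rescues).
* **Simulation machinery.** `builtin_scenario("A")` … `"H"` reproduce
  the eight reference scenarios (200/arm, 5,000 probes, sd 0.3);
  `simulate_trial()` / `simulate_survival_cohort()` generate cohorts
  with known subgroup truth; `run_scenario_experiment()` sweeps
  scenarios x classifiers x replicates into operating-characteristic and
  power tables; `expected_confusion_or()` computes the deterministic
  odds-ratio attenuation caused by a given sensitivity/specificity.
* **User data.** `classify_user_data()` takes an expression TSV plus a
  clinical TSV (binary response, or time + event), auto-detects the
  endpoint, and returns the cross-validated assignment and comparison
  report. `inst/cli/adaptsig.R` wraps simulate / experiment / classify
  for shell use.

## Worked example

Simulate one trial from scenario E (pi = 0.1, u11 = 0.8, all other
cells 0.2), screen, classify with cross-validated DLDA, and test:

```r
library(adaptsig)
sc <- builtin_scenario("E")
co <- simulate_trial(sc, seed = 1)

screen_markers(co)
#> Predictive marker set U: 15 probes (interaction p <= 0.001)
#>  probe_id   beta2   beta3   p_value
#>      4235 -0.2759 -3.1124 5.814e-06
#>         8  0.7282  0.7185 9.292e-06
#>  ...

a <- cross_validated_assignment(co, dlda_method(), n_folds = 10, seed = 1)
confusion_metrics(a$label, co$subgroup)
#> Confusion (g+ positive): tp=38 fp=0 tn=362 fn=0
#>   sensitivity=1.000  specificity=1.000  ppv=1.000  npv=1.000  accuracy=1.000

run_comparisons(co, a)
#> Subgroup comparisons (binary endpoint)
#>   Comparison 1 ctrl vs trt, all patients  p = 0.4524
#>   Comparison 2 ctrl vs trt, g+            p = 0.02241
#>   Comparison 3 ctrl vs trt, g-            p = 0.3555
#>   Comparison 4 g+ vs g-, treatment arm    p = 4.272e-06
#>   Comparison 5 g+ vs g-, control arm      p = 0.7456
#>   overall test at 0.02: not significant; g+ subgroup at 0.03: significant
```

The screen recovers all 10 true markers (probes 1–10) plus five false
positives; the cross-validated DLDA assignment is perfect on this draw;
and the testing strategy shows exactly the situation the design exists
for — the all-patients test misses the diluted overall effect
(p = 0.45) while the marker-positive subgroup test detects it at its 3%
allocation.

The deterministic attenuation calculator reproduces the cost of a
noisier classifier:

```r
expected_confusion_or(sc, sensitivity = 0.991, specificity = 0.644)
#> Expected predicted-g+ stratum (sens 0.991, spec 0.644):
#>        arm responders non_responders
#>    control         17             67
#>  treatment         29             55
#>   expected false-positive g- patients per arm: 64
#>   odds ratio attenuated to 2.08 from the true 16.00
```

Scenario sweeps (here small; the reference tables use 1,000 replicates):

```r
ex <- run_scenario_experiment(c("A", "E"), n_replicates = 200,
                              master_seed = 42)
ex$metrics   # mean |U|, true positives, sens/spec/PPV/NPV/accuracy
ex$power     # overall-significant, subgroup-rescue, overall power
```

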