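---
title: "Methods: subgroup identification and testing in adaptive signature designs"
author: "adaptsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgroup identification and testing in adaptive signature designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptsig)
```

## The problem

A randomized two-arm trial compares an untreated control with a new
treatment that is expected to help only a *marker-positive* subpopulation
(`g+`), identified by high-dimensional genomic measurements collected
before treatment. Two things must happen inside a single study: (1) a
classifier must be built that assigns each patient to `g+` or `g-`, and
(2) treatment effect must be tested in all patients and in the selected
subgroup without inflating the study-wise type-I error. `adaptsig`
implements both halves — the classifiers, the cross-validated assignment
that keeps classifier development honest, the five-comparison testing
strategy with split alpha, and a simulator for studying the operating
characteristics of the whole design.

## The data model

Patients belong to latent subgroups `g+` (prevalence $\pi$) and `g-`.
The binary response is Bernoulli with cell probabilities $u_{it}$
($i \in \{g-, g+\}$, $t \in \{\text{control}, \text{treatment}\}$),
ordered $u_{00}, u_{01}, u_{10} \le u_{11}$: only `g+` patients under
treatment enjoy the elevated response rate. Each of $m$ probes is Normal
with standard deviation $\sigma$; a truly predictive probe is centred at
the log-odds of the responder rate its subgroup attains under treatment,
$x = \mathrm{logit}(u)$ with $u = u_{11}$ for `g+` and $u = u_{01}$ for
`g-` patients, *in both arms* — expression is measured pre-treatment, so
treatment cannot shift it. Non-predictive probes are centred at 0 for
everyone.

Two readings of the probe-mean rule are possible; the per-(subgroup, arm)
alternative would give `g+` control patients the `g-` mean, destroying the
association between expression and subgroup that the reference
sensitivities (near 1 in the strong-effect scenarios) require. The
subgroup-only reading is therefore built in; it is also the only one
consistent with pre-treatment measurement. Whether the predictive probes
share one mean or get jittered per-probe means is similarly unstated;
identical means are used, which makes the per-probe screening power
homogeneous and easy to reason about.

The eight reference scenarios A–H (see `builtin_scenario()`) use 200
patients per arm, 5,000 probes, $\sigma = 0.3$, and interaction screening
at 0.001. Subgroup membership is drawn i.i.d. Bernoulli($\pi$) — $\pi$ is
a population proportion, not a fixed count.

What the simulator deliberately does *not* emulate: gene–gene
correlation, batch effects, missing values, heterogeneous `g+`
subpopulations, or platform-specific intensity distributions. Passing the
simulation benchmarks therefore demonstrates correctness of the
*procedure* under the stated generative model, not performance on any
particular real microarray cohort.

## Marker screening

For each probe $z_k$ the generalized linear interaction model

$$ h(y_{kt}) = \beta_{0k} + \beta_{2k} t + \beta_{3k} (z_k t) $$

is fitted (logit link for binary endpoints; Cox partial likelihood for
survival, where there is no intercept). Note the deliberate absence of a
main effect of $z_k$: the printed model is implemented exactly as stated.
A probe enters the candidate set $U$ when the two-sided Wald test of
$\beta_{3k} = 0$ is significant at `alpha_screen` (default 0.001); no
multiplicity correction is applied, since the level is already a
stringent per-probe threshold. The Wald statistic was chosen over the
likelihood ratio because it is the convention in this literature and
cheapest at genome scale; `fit_interaction_model(..., test = "LRT")`
exposes the alternative, and the two agree closely away from separation.

Because the model has no $z_k$ main effect, its likelihood factorizes
over arms: control patients inform only $\beta_{0k}$ (whose ML estimate
is the logit of the control response rate, identical for every probe),
and the treatment arm is a two-parameter logistic fit. The genome-wide
scan exploits this in compiled code — a per-probe 2x2 Newton iteration
over treated patients — which is exact maximum likelihood for the full
model and leaves the Wald standard error of $\beta_{3k}$ unchanged
(Fisher information is block diagonal in the reparametrization). The
suite verifies scan-vs-`glm()` agreement to ~1e-6.

Degenerate probes — constant values, all-equal responses, complete or
quasi-separation (coefficient magnitude above 30) — are flagged
non-converged and assigned p = 1 rather than raising an error: a
5,000-probe scan must not abort on one pathological column. A
consequence worth knowing: if the response is *deterministically* linked
to a marker, the logistic ML estimate diverges and the probe is
(correctly) dropped; the screening test has its best power at strong but
finite effects. For survival endpoints, screening ranks probes by the
interaction p-value of per-gene Cox fits and keeps the smallest
`top_k` (default 5) — a fixed-size selection suited to the small cohorts
typical of survival reanalyses, where a fixed p threshold would often
return nothing.

Because the cross-validated pipeline only ever screens inside training
folds, the marker accounting that `run_scenario_experiment()` reports
(`significances`, `true_positives`) is the mean selected-marker count
over the training folds — at the reference design (10 folds of a
400-patient trial) that is screening at n = 360, whose power is
noticeably below a hypothetical full-cohort screen. This is the level at
which the procedure actually operates, and it is the level at which the
reference operating characteristics are reproduced.

## Classifiers

**DLDA** (binary endpoints). Gaussian maximum likelihood with a common
diagonal covariance: per-class, per-feature means, per-feature variance
pooled across the two classes, empirical class priors. The discriminant
$\sum_k -(x_k - \mu_{ck})^2 / (2 s_k^2) + \log \pi_c$ is linear, needs no
matrix inversion, and its boundary depends only on means and variances,
which is what makes it robust to the heavy class imbalance that subgroup
classification produces. Pooling (rather than class-specific variances)
is what keeps the rule linear; variances are floored at
`1e-8 * mean(variance)` so a degenerate feature cannot produce an
infinite score. Score ties go to `g-` — when the evidence is exactly
balanced the patient is not assigned to the treatment-benefit group. No
shrinkage is applied to the means: plain DLDA is the contract, and a
shrunken variant would introduce a tuning intensity that the design does
not specify.

*Training labels.* The design never observes the true subgroup. For a
binary response the observable correlate of treatment benefit is the
treatment-arm outcome, so DLDA trains on treatment-arm patients with
responder/non-responder as the class label; control-arm patients are
excluded because their response carries no benefit signal when the
control rates of the two subgroups coincide ($u_{10} = u_{01}$). Training
on both arms is available (`dlda_method(train_arms = "both")`) for
sensitivity analysis. This reading matters: the reference operating
characteristics depend on it, and it is recorded here because the source
design leaves it implicit.

**ASD voting rule.** The original adaptive-signature classifier: marker
$i \in U$ votes for a patient when the fitted per-marker log odds ratio
of treatment benefit, $\beta_{2i} + \beta_{3i} x_i$, *strictly exceeds*
$\ln R$; the patient is `g+` when at least $G$ markers vote. Raising
$\ln R$ or $G$ can only shrink the voted-in set, so sensitivity is
non-increasing and specificity non-decreasing along
$(1,1) \to (2,2)$ — a monotonicity the suite asserts. Negative $\ln R$
thresholds are meaningful for survival endpoints, where the per-marker
score is a log hazard ratio and benefit means reduced risk.

**Cox risk score with survival cutoff** (survival endpoints). A
multivariable Cox model over the screened markers (genes only, no
treatment covariate — the score captures biology, not allocation) gives
the linear predictor $l(x) = \sum_l b_l x_l$; the Breslow baseline
converts it to a predicted survival probability
$S(\tau \mid x) = S_0(\tau)^{\exp l(x)}$ at the horizon $\tau$ (default
5 years), and patients with $S(\tau \mid x) \ge 0.5$ are labelled `g+`.
The tie goes to `g+`: a patient predicted to have even odds of surviving
the horizon is given the benefit of the doubt. A horizon beyond the last
observed event time falls back to the last baseline value with a
warning. The cutoff itself classifies; re-training DLDA on the
cutoff-derived labels is a conceivable variant but adds an estimation
layer without new information, so it is not the default path.

## Cross-validated assignment

`cross_validated_assignment()` draws folds once from the seed, cyclically
over the arm-blocked shuffled patient order — this stratifies by arm (so
every training set contains both arms, which screening requires) and
reduces exactly to leave-one-out when the fold count equals the patient
count. Within each training fold the markers are re-screened and the
classifier re-fitted from scratch; held-out patients are labelled by a
model that never saw them. A fold whose screen returns no markers labels
its held-out patients `g-` (no signature, no selection) and records the
fact in the fold audit. The audit (training/test indices and selected
markers per fold) makes the no-leakage property checkable after the
fact, and the suite additionally verifies that a leave-one-out label
equals a manual refit without that patient.

## The testing strategy

Five comparisons are reported: control vs treatment in all patients (1),
in predicted `g+` (2), in predicted `g-` (3); `g+` vs `g-` within the
treatment arm (4) and within the control arm (5). The study-wise error
$\alpha$ (default 5%) is split as $\alpha_1$ (default 2%, one-sided) for
the all-patients test and $\alpha_2 = \alpha - \alpha_1$ (3%) for the
`g+` test. Binary endpoints use Fisher's exact test — exact at the small
`g+` strata the design produces — one-sided in the direction of
treatment benefit for Comparisons 1–2 (matching the one-sided
allocation; the sidedness of 3–5 is not pinned down by the design, and
two-sided is the conservative reporting choice there). Survival
endpoints use the logrank test. Comparison 2 is always computed: the
strategy tests both primary hypotheses with split alpha, unlike the
legacy sequencing in which the subgroup was examined only after an
overall failure. That legacy accounting still defines *overall power* in
`summarize_power()`: replicates where Comparison 1 rejects at $\alpha_1$,
plus replicates where it fails but Comparison 2 rejects at $\alpha_2$.
Under a global null this two-test procedure spends at most
$\alpha_1 + \alpha_2$, and the suite checks the realized study-wise
rejection rate stays at or below $\alpha$ (Fisher's exactness makes it
conservative in practice). A comparison whose stratum is empty is
flagged not-evaluable rather than given a fabricated p-value.

## Misclassification and odds-ratio attenuation

`expected_confusion_or()` quantifies what an imperfect classifier costs:
for a scenario and a (sensitivity, specificity) pair it forms the
expected per-arm responder table among predicted-`g+` patients —
$\mathrm{sens} \cdot \pi n$ true positives plus
$(1-\mathrm{spec})(1-\pi) n$ false positives per arm, each contributing
responders at its cell probability — and compares the resulting odds
ratio with the true subgroup odds ratio
$[u_{11}/(1-u_{11})] / [u_{10}/(1-u_{10})]$. Expected counts are rounded
half-up to whole patients by default, reproducing printed-table
arithmetic; `round_counts = FALSE` keeps the calculator continuous and
exactly monotone in both operating characteristics. For scenario E and a
classifier at sensitivity 0.991 / specificity 0.644 the true odds ratio
of 16 collapses to about 2.08 — the motivating illustration for caring
about classifier accuracy at all.

## Numerical and design choices

* **Seeds.** Every stochastic entry point takes an explicit seed.
  Experiment sweeps derive a child seed per (scenario, replicate) by
  mixing the indices into the master seed with fixed prime multipliers
  (mod $2^{31}-19$), so any replicate is reproducible in isolation and
  the sweep is reproducible end to end.
* **Newton safeguards.** The screening scan caps coefficients at |30|
  (separation), requires the 2x2 information determinant to stay away
  from zero (constant interaction column), and iterates to a step below
  1e-10 — except that probes whose Wald statistic is clearly below 1.5
  may stop at a step below 1e-5, where the residual drift in p (~1e-9)
  is irrelevant to any screening threshold; the accept rule is fixed, so
  p-values are deterministic and screening remains monotone in the
  level.
* **Ties.** DLDA tie to `g-`; ASD strict `>`; survival cutoff tie to
  `g+`. All three are stated contracts, not accidents of floating point.
* **Zero denominators.** Operating-characteristic ratios with empty
  denominators (no predicted positives, say) are `NA` with the counts
  reported alongside, and scenario sweeps average over the replicates
  where a metric is defined.
* **Problem sizes.** The packaged replication runs use 200 replicates
  per scenario (the reference tables use 1,000), with comparisons made
  at 3 Monte-Carlo standard errors; the expanded sweep is one argument
  away (`n_replicates = 1000`).

## Known limitations

The simulator's independence assumptions (above) mean the reported
operating characteristics are upper bounds on what correlated, batched,
heterogeneous real data would give. The Wald screen loses power against
near-deterministic marker–response relationships (separation), where it
deliberately drops probes rather than chasing divergent estimates. The
survival branch's reference analyses require external cohort data, so
its checks are property-based (planted-gene recovery, closed-form
Breslow, separable-cohort accuracy) rather than table replication.
The $\alpha_1/\alpha_2$ split is taken as given; optimizing the
allocation is out of scope.
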