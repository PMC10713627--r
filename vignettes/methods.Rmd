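---
title: "Methods: high-throughput target trial emulation and balance-aware propensity model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-throughput target trial emulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Repurposing an approved drug for a new indication can be screened
observationally: mimic, for each candidate drug, the protocol of the
randomized trial one would like to run (eligibility, treatment assignment at
a well-defined time zero, follow-up, intention-to-treat contrast), and
estimate the drug's association with the outcome after adjusting for
baseline confounding. `ttescreen` implements such a screen for a
neurodegeneration setting: patients with mild cognitive impairment (MCI) are
followed for incident Alzheimer's disease (AD) after initiating a candidate
drug versus a comparator drug. Everything is organized around emulating many
trials per drug, diagnosing covariate balance honestly, and only trusting
effect estimates from emulations that actually balanced.

## Trial protocol

For a target drug, the **index date** is the first prescription, valid only
when a second fill of the same ingredient occurs at least 30 days later (a
new-user, repeat-fill initiation rule). Eligibility at index: an MCI
diagnosis strictly before index, age at the first MCI diagnosis at least 50,
at least 365 days of database history before index, and no AD (or related
dementia) diagnosis in the 1825 days before index. Follow-up runs five years
(1825 days; 730 days as a sensitivity horizon): the first AD diagnosis in
`(index, index + follow-up]` is an event at its day count; a patient whose
end of data (last diagnosis or prescription, whichever is later) reaches the
horizon is a negative event at the full horizon; anyone else is censored at
their end of data. All window arithmetic is integer day counting with one
month = 30 days, one year = 365 days, five years = 1825 days: time-to-event
definitions are day-level, and fixed day counts keep every rule
deterministic.

Each drug is emulated up to 100 times: 50 comparison arms built from
eligible initiators of one randomly drawn alternative ingredient, and 50
from initiators of a drug in the same ATC level-2 therapeutic class (an
active-comparator design). Comparison arms exclude anyone in the treated arm
or with any target-drug prescription before their own index. Drugs with
fewer than 500 eligible treated initiators are skipped. Comparator
ingredients are drawn without replacement across a mode's emulations while
the catalog allows (maximizing comparator diversity), with replacement once
exhausted — the protocol leaves recurrence unspecified, and this choice keeps
small catalogs usable.

**Covariates.** 267 baseline covariates: age, gender, 64 comorbidity-category
indicators, indicators for the 200 most prevalent prescribed ingredients,
and the MCI-to-index time lag. Indicators use any occurrence *strictly
before* the index date — including the index day would leak assignment-day
information. Two deliberate choices where the protocol is silent: the age
covariate is anchored at the index date (eligibility uses age at MCI — the
two anchors differ by the lag covariate, which is itself adjusted for), and
the top-200 medication list is computed once from the full study population
and frozen, so a covariate column means the same thing in every emulation of
a dataset. Age and lag are continuous; everything else is 0/1. Demographics
(birth date, sex) travel in a separate table beside the event stream, since
they are not events.

## Weighting and balance

The propensity score `e(x) = P(Z = 1 | X = x)` is estimated by a binary
classifier; subjects are weighted by trimmed **stabilized IPTW**

> `w = Z P(Z=1) / e(X) + (1 - Z) P(Z=0) / (1 - e(X))`

with `P(Z=1)` the empirical treated fraction of whatever subset the weights
are computed on (train, test, or combined — each partition is weighted
independently). Predicted scores are clipped to `[1e-6, 1 - 1e-6]` so
weights stay finite under separation. The top 1% smallest and biggest
weights are trimmed; trimming is implemented as *winsorization* (capping at
the pooled 1st/99th percentile weight values) rather than subject exclusion,
which keeps the sample size fixed — an assumption the balance formulas below
rely on. Pooled rather than per-arm trimming is used; an exclusion variant
was considered and rejected because dropping subjects changes the estimand
of every downstream formula.

Balance is diagnosed by the standardized mean difference per covariate,
`SMD = |mu_t - mu_c| / sqrt((s2_t + s2_c) / 2)`, with weighted means and
variances

> `mu_w = sum(w x) / sum(w)`,
> `s2_w = sum(w) / ((sum w)^2 - sum(w^2)) * sum(w (x - mu_w)^2)`

which reduce to the ordinary unbiased (n−1) sample formulas under unit
weights (asserted to machine precision in the tests). One SMD formula is
applied to all 267 covariates, continuous and binary alike. A covariate is
unbalanced when `SMD > 0.1` (the boundary counts as balanced); a trial is
balanced when at most 2% of its covariates are unbalanced, as a real-valued
bound (for D = 267 the cutoff is 5.34, so 5 passes and 6 fails). A covariate
constant in both arms gets SMD 0 when the means agree and infinity
otherwise: equal constants are perfectly balanced, differing constants are
maximally unbalanced, and the convention keeps padded all-zero schema slots
harmless.

## Balance-aware model selection

Three model families with fixed grids: regularized logistic regression
(L1, L2, none × 13 inverse strengths `10^-3 … 10^3`; the `none` regularizer
is an unpenalized fit, not a vanishing penalty), gradient-boosted trees
(depth 3–5 × max leaves 5–105 × min samples per leaf 200–300), and
feed-forward networks (five hidden layouts × two learning rates × four
weight decays, 15 epochs, batch 128). The network trainer is a small
in-package minibatch Adam implementation with decoupled L2 weight decay. The
inverse strength `C` maps to the elastic-net penalty scale as
`lambda = 1 / (n C)` because the underlying solver averages the loss over
subjects. The gradient-boosting "minimum samples per leaf" grid is mapped to
the booster's hessian-based `min_child_weight`, its closest control.

Selection is K-fold cross-validation (K = 10; folds stratified by treatment
and seeded — the stratification guarantees both classes in every fold) in
which, for each hyperparameter setting and fold, the model is trained on the
remaining folds and **two different quantities** are recorded: the
post-weighting unbalanced-covariate count on the *whole training set* using
the fold model, and the AUC (and cross-entropy) on the *held-out fold only*.
The balance-aware strategy picks the setting minimizing the mean unbalanced
count, breaking exact ties (float equality — a literal reading; grid order
gives the final deterministic tiebreak via strict-inequality updates) by the
larger mean validation AUC. The two baseline strategies pick the best mean
validation AUC or validation loss. The winner is refit on the full training
set. A nested variant (10 outer × 5 inner folds) reruns the whole selection
per outer-training partition and reports each inner winner's held-out
performance; its final model is the flat selection on the full training set.
Each emulation is split 80:20 (stratified by treatment, seeded) into the
training data that drives selection and a test set used only for the
three-partition balance evaluation (train / test / combined, each weighted
independently).

Logistic penalty grids are fitted as one regularization path per penalty per
fold, and single refits reuse the same path, so grouped and individual fits
agree exactly — this is what makes the brute-force selection oracle in the
test suite able to demand exact agreement.

## Estimation, aggregation, screening

Per trial, the adjusted hazard ratio (aHR) is the exponentiated treatment
coefficient of a weighted Cox proportional-hazards fit with a robust
(sandwich) variance — the model-based variance is invalid under estimated
weights, so the sandwich is used even though only a Wald test is reported.
The adjusted survival difference is the weighted Kaplan-Meier treated-minus-
control survival at the end of follow-up. Per drug, estimates from
*balanced* trials only are aggregated: the mean aHR with a percentile
bootstrap confidence interval over B = 1000 resamples of the trial-level
aHRs (resampling emulations, not patients), and a one-sided bootstrap
p-value for the mean aHR being below 1 (the fraction of bootstrap means at
or above 1 — the screening hypothesis is directional). Percentile rather
than BCa intervals: the aggregate is a plain mean of a modest number of
trial-level estimates. Non-converged Cox fits are dropped with a flag rather
than failing the drug — at high throughput a single pathological emulation
must not kill a screen.

A drug is a repurposing candidate when, in every supplied dataset: at least
10% of its emulations balanced; the aHRs of *all* balanced trials are below
1 (a documented relaxed mode requires only the mean below 1 — the strict
rule is the methods-faithful default); and the bootstrap p-value clears the
Bonferroni-corrected level `alpha / m`, with `m` defaulting to the number of
drug-dataset hypotheses actually tested in the run (overridable to reproduce
a fixed historical threshold such as 0.05/312 = 1.6e-4). Candidates are
ranked by mean aHR.

## The synthetic EHR generator

Real clinical data warehouses are access-restricted, so the package ships a
generator whose output exercises every pipeline rule with known ground
truth. Per patient: a first-record date spread over the enrollment span; an
MCI diagnosis 365–1000 days later (so most patients clear the history rule);
age at MCI drawn Normal(72, 8) truncated to 45–95 (a small fraction under 50
exercises the age rule); 64 comorbidity categories as independent Bernoulli
draws with category prevalences Uniform(0.05, 0.25). The first eight
categories act as confounders: their count raises both the log-odds of
receiving the target drug (base rate 0.12) and the outcome log-hazard, each
scaled by `confounding_strength`. Prescription streams have
geometric-plus-offset inter-fill gaps (offset 10 days, mean ≈ 35), so the
30-day two-fill rule sees both passing and failing patients; fill counts are
1 + Geometric(0.35), so single-fill patients exist too. The AD outcome is
drawn from an exponential proportional-hazards model (constant baseline
hazard, default 1e-4/day) with treatment coefficient `true_log_hr` — the
simplest generator satisfying the Cox assumptions the estimation module
relies on, which keeps recovery checks analytic. `plant_edge_cases()`
appends one labeled patient per eligibility rule violation plus one fully
compliant comparator patient, and the tests assert each is excluded for
exactly the matching reason.

What the generator does **not** emulate: real ICD/NDC coding distributions,
site effects, informative censoring, time-varying confounding, or
measurement error. Passing tests on this generator demonstrate that the
pipeline's logic is correct under its own assumptions — not that those
assumptions hold in any particular real database. Note also that the
generator's conditional hazard ratio is not the marginal one: with
heterogeneous hazards the marginal Cox coefficient is attenuated toward the
null (non-collapsibility), so recovery checks are framed comparatively
(adjusted closer to the planted effect than unadjusted) rather than as
exact recovery.

## The simulation study

A fixed 267-covariate generating model for evaluating the estimator end to
end: six structured covariates (two correlated Bernoulli pairs, three
Gaussians with one dependence) plus 261 independent Bernoulli background
covariates; treatment assigned by a logistic model in either a linear form
(intercept −6.84) or a nonlinear form in which most effects act only through
interactions with X1 (intercept −5.72); and Weibull (shape 2) event times
`T = 100 sqrt(-log U / exp(eta))` with conditional treatment log-hazard −1
and outcome intercept −5.67, administratively censored at 200 days with no
other censoring. The event rule is `T* < 200` (an exact tie censors — a
measure-zero convention stated for determinism).

Because the hazard ratio is non-collapsible, the estimand is the *marginal*
HR, obtained by generating a large population with **both** potential
outcomes per subject — using a shared uniform draw per subject (common
random numbers reduce oracle variance without biasing the marginal fit) —
censoring both at 200, and fitting a Cox model with treatment as the sole
covariate on the stacked rows. At 200,000 subjects this yields ≈ 0.578
(conditional `exp(-1) ≈ 0.368`), with Monte-Carlo error comfortably inside
±0.02; the package uses 200,000 as its reference population size, which a
single core computes in seconds.

The replication grid crosses sample size (3000–5000 in steps of 500),
assignment mechanism (linear, nonlinear) and treatment-model specification
(correct, incorrect): 20 scenarios. The *incorrect* specification in the
linear scenario squares the three binary covariates — a no-op for 0/1
values, so its effective misspecification is adding the inactive X1 and X4
main effects; the squaring is kept literally because it is the only
reproducible reading of that design. The nonlinear scenario's incorrect
design uses raw
main effects, omitting every generating interaction. Balance is always
diagnosed on the raw 267 covariates regardless of what design the treatment
model sees. Per replicate the data are split 80:20, the logistic grid is
cross-validated once, each selection strategy picks its winner from the
shared CV table (the fits are identical across strategies, so sharing is
exact, not an approximation), and the winner's trimmed stabilized weights
feed a weighted Cox fit on the combined data. Scenario metrics: balanced
fraction, mean unbalanced counts before/after weighting, HR mean, oracle SD
(the across-replicate SD), bias, MSE, and Wald coverage of `psi_b ± 1.96
sigma` computed on the HR scale, matching the metric's definition; a
log-scale `coverage_scale` option is provided but non-default, since HR
sampling distributions are closer to normal on the log scale and the choice
of scale is a genuine ambiguity.

**Problem sizes.** The package's own evaluation runs use 25 replicates per
scenario and a 200,000-subject truth population; the full 100-replicate,
1,000,000-subject configuration is a parameter change, not a code change.

## Known limitations

No per-protocol or time-varying exposure analysis; censoring is assumed
non-informative; no competing-risk handling; the sequence-model propensity
family (visit-history recurrent networks) is out of scope — the covariate
interface is cross-sectional; no variance-ratio or KS balance diagnostics
(balance is defined solely via SMD); Bonferroni is the only multiplicity
control. The drug vocabulary is abstracted to `code → ingredient → ATC-L2`
maps rather than reproducing any particular coding system.
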