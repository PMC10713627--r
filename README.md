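# ttescreen

High-throughput target trial emulation for drug-repurposing screens from
longitudinal patient records.

## What it does, and for whom

Observational drug-repurposing screens ask, for each of hundreds of approved
drugs, whether initiating that drug is associated with a lower risk of some
outcome — here, incident Alzheimer's disease (AD) among patients with mild
cognitive impairment (MCI). `ttescreen` is for epidemiologists and
biostatisticians who want to run that screen as a *target trial emulation*:
every drug is evaluated by emulating many randomized trials (new-user
design, random and active ATC-L2 comparators, intention-to-treat follow-up),
adjusting for high-dimensional baseline confounding with inverse probability
of treatment weighting (IPTW), and only trusting emulations whose covariates
actually balance.

The methodological core is **balance-aware propensity-score model
selection**. A propensity model `e(x) = P(Z=1|X=x)` yields trimmed
stabilized weights

    w = Z * P(Z=1) / e(X) + (1 - Z) * P(Z=0) / (1 - e(X))

and per-covariate balance is measured by the weighted standardized mean
difference, `SMD = |mu_t - mu_c| / sqrt((s2_t + s2_c)/2)`, with a covariate
unbalanced when SMD > 0.1 and a trial balanced when at most 2% of its D
covariates are unbalanced. Instead of picking hyperparameters by validation
AUC or loss (the default machine-learning practice), the package's K-fold
selection rule scores each candidate setting by the number of covariates its
weights leave unbalanced on the whole training set, breaking ties by
validation AUC. Per trial, the treatment effect is the adjusted hazard ratio
(aHR) from a weighted Cox fit with robust variance; per drug, balanced-trial
aHRs are aggregated with a 1000-replicate percentile bootstrap, and
candidates must pass a Bonferroni-corrected one-sided test and replicate in
every dataset.

Because real clinical data warehouses are access-restricted, the package
ships two fully specified data generators: a synthetic longitudinal EHR with
known treatment effect and confounding (so the cohort-to-screening pipeline
is testable end to end), and a 267-covariate confounded Weibull survival
simulation whose marginal ground-truth hazard ratio (~0.578, versus the
conditional exp(-1) ~ 0.368 — hazard ratios are non-collapsible) is computed
by a potential-outcomes Cox fit.

## Worked example

Generate a synthetic EHR with a planted protective effect (HR 0.6) and
confounding, emulate trials for the target drug, select a propensity model
by the balance-aware rule, and estimate the adjusted hazard ratio:

```r
library(ttescreen)

sim <- generate_ehr(ehr_sim_config(
  n_patients = 6000, n_ingredients = 10,
  true_log_hr = log(0.6), confounding_strength = 0.5, seed = 3001))

cfg <- run_config(seed = 3001, min_treated = 100, n_emulations_per_drug = 6)
trials <- emulate_drug(sim$events, sim$demographics, sim$vocab,
                       target_drug = "ING0001", config = cfg)
tr <- trials[[1]]

sel <- select_cv(tr$X, tr$Z, ps_model_space("LR"), k = 3,
                 strategy = "balance_auc", seed = 3001, config = cfg)
w   <- stabilized_iptw(predict_ps(sel$model, tr$X), tr$Z, cfg$trim_quantile)
bal <- balance_report(tr$X, tr$Z, w$weights, cfg)
adj   <- weighted_cox(tr$Z, tr$Y, tr$T, w$weights)
unadj <- weighted_cox(tr$Z, tr$Y, tr$T)

cat(sprintf("unbalanced covariates: %d -> %d (balanced: %s)\n",
            bal$n_unbalance_before, bal$n_unbalance_after, bal$balanced_after))
cat(sprintf("unadjusted HR %.3f | adjusted aHR %.3f (planted 0.6)\n",
            unadj$ahr, adj$ahr))
```

Output from this exact invocation:

```
unbalanced covariates: 14 -> 3 (balanced: TRUE)
unadjusted HR 0.820 | adjusted aHR 0.687 (planted 0.6)
```

Confounded prescribing leaves 14 covariates unbalanced before weighting; the
selected logistic propensity model's weights bring that down to 3 (within
the 2% criterion, so the trial counts as balanced), and the weighted Cox
estimate moves from the confounding-attenuated unadjusted value toward the
planted protective effect. (A single emulation is noisy; the test suite
repeats this comparison over 20 seeds and up to 6 emulations each, where the
adjusted mean is reliably closer to log 0.6 than the unadjusted mean.) The
simulation side is one call:

```r
metrics <- run_grid(sizes = 3000, mechanisms = "linear",
                    specifications = "correct",
                    strategies = c("balance_auc", "val_auc"),
                    n_replicates = 25, seed = 1)
```

returning, per scenario and strategy, the balanced-replicate ratio, mean
unbalanced-covariate counts before/after weighting, HR mean and oracle SD,
bias, MSE and Wald coverage against the potential-outcomes ground truth.

A thin command-line driver wraps the same functions
(`inst/cli/ttescreen.R`): subcommands `simulate-cohort`, `emulate`,
`select-ps`, `estimate`, `screen`, `simstudy`, each seeded and writing a run
manifest so identical invocations reproduce identical files.

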