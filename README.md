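# actisleep

Sleep–wake, sleep-stage, nonwear and daytime-nap classification from **raw
tri-axial wrist accelerometry**, scored on the standard 30-second epoch grid.

Wrist-worn accelerometers are the workhorse of large-scale sleep epidemiology:
they are cheap, unobtrusive, and wearable for weeks, but they record movement,
not sleep. This package implements a complete analysis stack for turning raw
acceleration (timestamped x/y/z in g, typically 25–100 Hz) into per-epoch
sleep phenotypes, for researchers who have polysomnography (PSG)-labelled
training data, sleep logs, or simply raw recordings to score:

- **Derived signals** —
  `ENMO = max(0, sqrt(ax² + ay² + az²) − 1)`, the gravity-removed movement
  magnitude; the **z-angle** `atan(az / sqrt(ax² + ay²)) · 180/π` over rolling
  5-s axis medians, a posture indicator; and **LIDS**
  `= 100 / (activity count + 1)`, where the activity count is a 10-min moving
  sum of `max(0, ENMO − 0.02)`, smoothed over 30 min — a nonlinear inversion
  of locomotor activity that tracks ultradian sleep cycles.
- **Epoch features** — 13 statistical measures (mean, SD, min, max, MAD,
  20/200-bin entropies, and previous/next mean differences at 30/60/120 s)
  applied to each derived signal per 30-s epoch (39 columns; a 36-column
  preset is available).
- **Heuristic baselines** — the van Hees posture-angle rule (no z-angle change
  > 5° sustained ≥ 5 min ⇒ sleep) and the Sadeh and Cole-Kripke activity-count
  algorithms with their published coefficients, fed by a zero-crossing count
  derivation.
- **Random-forest protocol** — SMOTE class balancing (training rows only),
  participant-grouped 5×5 nested cross-validation with a randomized search
  over trees ∈ {100,…,500} × depth ∈ {5,10,15,20,Full}, 5-min rolling
  smoothing of class probabilities, and an ensemble of the five outer-fold
  models.
- **Hierarchical sleep stages** — a local random forest per parent node of the
  class tree Root→{Nonwear, Wear}, Wear→{Wake, Sleep}, Sleep→{NREM, REM},
  NREM→{N1+N2, N3}, N1+N2→{N1, N2}, with hierarchical precision/recall/F1
  computed over ancestor closures.
- **Nap detection** — combining the sleep–wake and wear–nonwear ensembles
  (nonwear takes precedence) and extracting sleep episodes ≥ 15 min outside
  the sleep-period time window, with paired t-test / Pearson comparison
  against self-report.
- **Synthetic recordings** — a generator of labelled multi-hour recordings
  (heavily diagonal sleep-stage Markov chain, state-dependent movement bursts
  and posture changes, nonwear stillness, gravity and sensor noise) so the
  entire stack is testable at desk scale without PSG data.

## Worked example

Train a sleep–wake ensemble on a simulated six-participant cohort and compare
it with the van Hees baseline on the same held-out epochs:

```r
library(actisleep)

cohort <- simulate_cohort(6, sim_config(duration_hours = 2), seed = 11)
epochs <- cohort_epoch_data(cohort)
x      <- epoch_features_matrix(epochs)
wear   <- !is.na(epochs$sleepwake)

fit <- nested_cv_train(x[wear, ], epochs$sleepwake[wear],
                       epochs$participant[wear],
                       training_config(search_draws = 4, inner_folds = 3,
                                       seed = 2))
fit
#> <trained_ensemble> task sleepwake: 5 members over classes {sleep, wake}
#>  fold trees depth  macro_f1  macro_ap     kappa n_val
#>     1   200    10 0.9254578 0.9654447 0.8509602   480
#>     2   400     0 0.9410348 0.9834476 0.8821218   240
#>     3   300    15 0.9781290 1.0000000 0.9562719   137
#>     4   500     0 0.9890306 1.0000000 0.9780622   240
#>     5   400    15 0.9394258 0.9883763 0.8790041   173

rep <- evaluation_report(fit$predictions$truth, fit$predictions$predicted,
                         probs = as.matrix(fit$predictions[, fit$classes]))
sprintf("pooled held-out macro F1 %.3f, macro AP %.3f, kappa %.3f",
        rep$macro_f1, rep$macro_ap, rep$kappa)
#> "pooled held-out macro F1 0.953, macro AP 0.986, kappa 0.906"

vh <- unlist(lapply(cohort, function(s)
  as.character(vanhees_classify(compute_z_angle(s$raw)))))
macro_f1(epochs$sleepwake[wear], vh[wear])$macro_f1
#> 0.791
```

Each row of `fit$outer_metrics` is one outer fold: the hyperparameters the
inner search chose (depth 0 means unbounded), and macro F1 / average precision
/ Cohen's kappa on that fold's held-out participants after probability
smoothing. The pooled numbers aggregate all held-out epochs; every epoch is
scored by a model that never saw its participant. On this synthetic cohort the
forest clearly beats the posture heuristic (0.95 vs 0.79 macro F1) — the same
qualitative ordering reported for real PSG cohorts, though synthetic data is
deliberately easier.

A command-line interface wrapping the same functions ships in
`inst/cli/actisleep` (subcommands `simulate`, `extract-features`, `classify`,
`train`, `predict`, `evaluate`, `detect-naps`, `run-all`).

## Scope notes

Input recordings are assumed gravity-calibrated upstream (e.g. by GGIR);
native binary device formats are out of scope — recordings are read from
delimited text with a small `#` header. The synthetic generator reproduces
the statistical structure the classifiers rely on, not human kinematics; see
the methods vignette (`vignettes/actisleep-methods.Rmd`) for what that does
and does not demonstrate.
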