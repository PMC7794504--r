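---
title: "Methods: signals, classifiers and design choices in actisleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signals, classifiers and design choices in actisleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures the package implements, the
parameters that matter, and the design decisions taken where a published
description leaves the implementation open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The epoch grid and derived signals

All labels, features and predictions live on a 30-second epoch grid anchored
at the first sample of the recording, with half-open epochs
$[t, t + 30\,\mathrm{s})$ and `n_epochs = floor(duration / 30 s)`. Axes are
in g; recordings are assumed gravity-calibrated upstream.

Three signals are derived from the axes $a_x, a_y, a_z$:

**ENMO** (per sample, g): $\max(0, \sqrt{a_x^2+a_y^2+a_z^2} - 1)$. A
stationary sensor has vector norm 1 g and ENMO exactly 0; the floor at zero
discards calibration undershoot.

**z-angle** (per 5 s, degrees): each axis is replaced by its rolling 5-s
median (a `runmed` window of `round(5 · sample_rate)` samples, forced odd),
the per-sample angle is $\arctan(a_z / \sqrt{a_x^2 + a_y^2}) \cdot 180/\pi$,
and per-sample angles are averaged into consecutive 5-s cells. The medians
make the angle a posture estimate robust to movement transients. A window in
which all three medians are zero cannot occur with a working sensor; it is
mapped to 0° with a warning rather than an error so that corrupt segments do
not abort batch processing.

**LIDS** (per epoch, dimensionless in (0, 100]): ENMO is thresholded at
0.02 g, averaged per epoch, summed over a centred 10-min (20-epoch) moving
window to form the *activity count*, inverted as $100/(\text{count}+1)$, and
smoothed with a centred 30-min (60-epoch) moving average. The constants 0.02 g
and 100 are fixed, not configurable: they define the statistic. Two
resolution choices are open in the usual verbal description and are pinned
here: the moving sum runs at **epoch** resolution (matching the 30-s analysis
grid and the count-based origin of the statistic), and all moving windows are
**centred with shrinking edges** — no padding, so edge epochs average over
whatever window support exists. Centred windows avoid phase shift relative to
the labels; the trade-off is that the first and last few epochs are smoothed
over less context. Whether the original used centred or trailing windows is
not recoverable; the choice is recorded in output provenance.

## Epoch features

Thirteen statistical measures are applied to each signal per epoch: mean, SD,
min, max, median absolute deviation (unscaled, `constant = 1`), Shannon
entropy of the 20-bin and 200-bin histogram, and previous/next
mean-difference features at 30, 60 and 120 s. Within-epoch distributions are:
raw samples for ENMO, the six 5-s cells for the z-angle, and — since LIDS is
natively per-epoch — the five consecutive smoothed LIDS values centred on the
epoch, so its spread measures capture the local trend.

Pinned conventions:

- *Entropy binning* is over the epoch's own `[min, max]` range with
  natural-log entropy; empty bins contribute zero and a constant epoch has
  entropy 0. Range-free binning makes the entropies shift- and
  scale-invariant, which the property tests assert.
- *Difference orientation*: `prevKdiff = mean(current) − mean(previous K s)`,
  `nextKdiff = mean(next K s) − mean(current)`. Edge epochs lacking the full
  K seconds of context get 0 ("no change") rather than a missing value,
  keeping the matrix dense for the forest.
- *12 vs 13 measures*: descriptions of this feature set disagree between
  twelve measures (36 columns) and the thirteen listed measures. The default
  spec implements all 13 × 3 = 39; a `"paper36"` preset drops `next120diff`
  (the measure most redundant with `next60diff`). Which single measure a
  36-column variant excluded is not decidable from the descriptions; the
  preset choice is this package's own.
- Feature normalization (fitted on training rows only) uses the population-SD
  convention; constant columns map to zero with unit scale.

## Heuristic baselines

**van Hees posture rule**: on the 5-s z-angle series, maximal runs in which
every successive difference is ≤ 5° and whose span is ≥ 5 min are sleep.
"Does not change by more than 5°" is operationalized as *step-wise*
differences, not cumulative drift from run start, tolerating slow postural
drift — the behaviour of the widely used reference implementation. The 5-s
labels reduce to 30-s epochs by majority, ties to sleep (conservative toward
the sleep-biased prior of overnight recordings). Relaxing the threshold can
only grow runs, so sleep labels are monotone in it (property-tested).

**Counts**: historical devices computed activity counts onboard; a raw-data
re-derivation is unavoidably this package's own. It band-pass filters the z
axis (0.25–3 Hz, 4th-order Butterworth, applied forward-backward for zero
phase, after demeaning to suppress filter edge transients) and counts
positive-going crossings of a 0.01 g dead-band per epoch. Filter band and
dead-band are pinned in configuration and provenance. Whether published
comparisons fed device counts or re-derived counts to the count-based
algorithms is not recoverable.

**Cole-Kripke (1992)**: $D = 10^{-5}(404 A_{-4} + 598 A_{-3} + 326 A_{-2} +
441 A_{-1} + 408 A_0 + 508 A_{+1} + 350 A_{+2})$, sleep iff $D < 1$.
**Sadeh (1994)**: $PS = 7.601 - 0.065\,\mathrm{AVG} - 1.08\,\mathrm{NATS}
- 0.056\,\mathrm{SD} - 0.703\,\mathrm{LG}$ over an 11-epoch window, sleep iff
$PS \ge 0$. Out-of-range epochs contribute zero activity. Both coefficient
sets are compiled constants from the cited originals; no rescoring variants.

## The random-forest protocol

Tasks are binary: sleep vs wake (wear epochs only) and wear vs nonwear.

- **Grouped folds**: participants, never epochs, are assigned to folds
  (round-robin after a seeded shuffle; sizes differ by ≤ 1), so no
  participant's epochs straddle a train/validation split.
- **Nested CV**: 5 outer folds estimate generalisation; per outer fold a
  randomized search (default 10 draws without replacement from the 30-cell
  grid trees ∈ {100, 150, 200, 300, 400, 500} × depth ∈ {5, 10, 15, 20,
  Full}) is scored by 5-fold inner CV on macro average precision, and the
  winner is refit on the whole outer-training split. All other forest
  parameters keep the `ranger` defaults, recorded in provenance. If an inner
  split loses a class entirely, folds are re-drawn, then stratified by
  participant class profile, then the inner fold count is reduced — an error
  only if even two folds cannot cover every class.
- **SMOTE** balances *training* rows only: each minority class is topped up
  to the majority count with rows $x + u(x_{nn} - x)$, $u \sim U(0,1)$,
  $x_{nn}$ one of the `k = 5` nearest same-class neighbours (k reduced with a
  warning for tiny classes). Validation and test rows never pass through it;
  the tests assert their counts end-to-end.
- **Smoothing**: class probabilities are smoothed per participant over a
  centred 5-min (10-epoch) rolling mean and renormalized to the simplex.
  Whether a "rolling" window was centred or trailing is open; centred avoids
  systematic label lag. Smoothing is applied per member *before* ensemble
  averaging (the per-member reading of the protocol).
- **Ensembling**: the five outer-fold models predict with their own
  normalization statistics; smoothed member probabilities are averaged with
  equal weights; the label is the argmax, ties to the class earlier in the
  sorted class order.

One fit-count note: with a randomized search of $d$ draws scored by $k$-fold
inner CV, each outer fold costs $d \times k$ inner fits plus one refit —
$5(dk + 1)$ total, not $5 \times 5$. A protocol in which each inner fold
trains exactly one model cannot evaluate more candidate hyperparameters than
folds; the randomized-search reading is implemented because a 30-cell grid is
otherwise unreachable.

## Hierarchical sleep stages

The class tree is Root→{Nonwear, Wear}, Wear→{Wake, Sleep}, Sleep→{NREM,
REM}, NREM→{N1+N2, N3}, N1+N2→{N1, N2}; N1 and N2 are grouped because they
are electrophysiologically closer to each other than N2 is to N3. One
ensemble per non-leaf node is trained under the same protocol on the epochs
truly descending from that node, with the child branch as target; a node with
fewer than two represented children degenerates to a constant predictor with
a warning. Decoding is greedy top-down (argmax child per node) — the
local-classifier-per-parent-node convention — so predicted paths are
root-consistent by construction.

Hierarchical P/R/F1 work on ancestor closures with the root excluded (it is
always correct and would inflate scores). The micro aggregate is
$hP = \sum_i |T_i \cap P_i| / \sum_i |P_i|$ and analogously for $hR$.
Per-class scores decompose the same counts by node membership: precision over
epochs predicted into the class's branch, recall over epochs truly under it
(the sub-population whose true leaf descends from the class). This
decomposition makes upper-level scores invariant to corruption at deeper
nodes only, which the tests assert, and reproduces the qualitative
degradation of performance down the tree on synthetic cohorts. For internal
nodes the positive-class score used in average precision is the probability
of the node's branch at its parent.

## Nap detection

Free-living epochs are labelled by combining the two ensembles with
**nonwear precedence** — a removed device cannot witness sleep, so a nonwear
call overrides a sleep call. Maximal runs of Sleep wholly outside every
sleep-period time window and lasting ≥ 15 min are nap episodes; a run
interrupted by a single non-sleep epoch is split (no gap tolerance —
documented, and deliberately strict so the ≥ 15-min rule is exact). Weekly
nap minutes are normalized as `total × 7 / recorded days`, mirroring
multi-day free-living recordings compared against weekly self-report; the
normalization is flagged in output provenance since published estimates do
not state one. Self-report comparison uses a paired t-test and Pearson
correlation; identical arrays yield a 0 mean difference with an undefined
(NA) t statistic, and zero-variance arrays an NA correlation with a warning.

## The synthetic-data generator

The generator replaces PSG cohorts for all testing. It emulates exactly the
structure the classifiers exploit:

- a 30-s Markov chain over {Wake, N1, N2, N3, REM, Nonwear} with heavily
  diagonal transitions (all self-transitions ≥ 0.8; transitions between sleep
  states are rare compared to remaining in one);
- per-state movement: epoch-level bursts (band-limited 0.5–2.5 Hz sinusoids,
  independent phase per axis) with probability/amplitude decreasing
  Wake → N3 and REM between wake and light sleep (twitches under atonia);
  posture changes redraw the gravity unit vector at decreasing rates;
- nonwear as a fixed orientation plus 2 mg sensor noise. Its 0.98
  self-transition gives contiguous removal blocks (mean dwell 25 min) rather
  than i.i.d. nonwear epochs; the configuration validates that nonwear noise
  keeps the per-15-min acceleration SD below the 13 mg wear threshold, so
  ground-truth labelling stays self-consistent;
- worn states carry 10 mg sensor noise — real wrists are never
  accelerometrically silent — which is also what separates a still sleeper
  from a removed device.

No quantitative per-stage movement statistics are available to match; the
defaults were chosen once to make the classes separable in the way real data
are (wake ≫ REM > N1+N2 > N3 in mean ENMO; posture changes frequent in wake,
rare in deep sleep), not to match human kinematics. Consequently, passing
label-recovery tests demonstrates that the pipeline *can* recover structure
it is pointed at — correct plumbing, no leakage, sane features — and says
nothing about accuracy on real PSG cohorts, device noise spectra, sleep
disorders, or brand transfer. Published real-data scores are not reproducible
from this package and are not targeted by it.

The ground-truth wear labeller implements the protocol rule: wear inside the
PSG interval; outside it, non-overlapping 15-min blocks (anchored at the
first sample outside the interval on each side) are wear iff the block's
acceleration SD exceeds 13.0 mg. "SD of the acceleration signal" is computed
as the mean of the three per-axis SDs — symmetric in the axes and consistent
with the heuristic tradition the threshold comes from. A trailing partial
block uses its own SD if ≥ 5 min, otherwise inherits its neighbour's label.
Unscored PSG epochs are excluded from training and metrics.

## Numerical and interface conventions

- Every stochastic step derives its seed deterministically from a master
  seed; the same seed reproduces recordings, folds, SMOTE rows and forests
  bit-identically. Seeds stay below $2^{31}$.
- Epoch tables are written with 17 significant digits so the write/read round
  trip is bit-exact; raw files carry ISO-8601 millisecond timestamps
  (rounded, not truncated) and a `#` header declaring units (g or m/s², the
  latter converted at 9.81 m/s² per g) and sample rate.
- Hypnogram alignment snaps offsets < 15 s to the epoch grid (logged) and
  shifts the grid to the hypnogram start for larger offsets; files use
  1-based epoch indices.
- Degenerate inputs fail loudly (non-stochastic transition matrix, duplicate
  timestamps, mismatched feature columns) unless a silent fallback is the
  field convention (all-wake output for count series too short for the
  Sadeh/Cole-Kripke windows).

## Problem sizes

The test suite and the label-recovery checks run on a simulated cohort of 10
participants × 2 h at 25 Hz (2,400 epochs, 1.8 M samples per participant),
with 4 search draws × 3 inner folds for the flat tasks and a reduced
(3-outer-fold, 2-draw) configuration for the five hierarchy nodes; chain
convergence is checked on a 10,000-epoch sequence and the ENMO ordering on a
60-h recording. These sizes keep the full suite under a couple of minutes on
one CPU while exercising every contract; all protocol-integrity assertions
(member counts, grid membership, leakage, SMOTE confinement) are invariant to
them.

## Known limitations

- The count derivation, SMOTE implementation and generator movement model are
  this package's own where no published specification exists; each is pinned
  by oracle tests rather than by comparison to an external artifact.
- Greedy top-down decoding cannot revise an upper-level mistake lower in the
  tree; no global path search is attempted.
- Sleep-period windows must be supplied (sleep log); detecting the main sleep
  period itself is out of scope, as are binary device formats and
  gravitational auto-calibration.
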