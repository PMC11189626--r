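---
title: "Stochastic models of navigation strategy in circular hole-board mazes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic models of navigation strategy in circular hole-board mazes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratmaze)
```

## The behavioural setting

`stratmaze` models navigation in an automated circular-arena maze whose
periphery carries 24 evenly spaced vestibules (entry chambers), one of which
is the goal. A trial starts in a randomly chosen vestibule at least two
door-intervals from the goal and ends when the animal enters the goal
vestibule. The atomic behavioural events are *vestibule visits*; the portion
of trajectory between two consecutive visits is a *segment*, whose signed
size is the number of door-intervals spanned along the shorter travel
direction (positive clockwise, 1 to 12 in magnitude). All analyses work in a
goal-aligned frame with vestibules indexed 0–23 clockwise and the goal at 0.
The labels on the circle are internal to the package: only the sign
convention for travel direction (clockwise positive) is externally
meaningful, so indexing direction was chosen to make positive steps
increment the index.

Four normalized distributions summarize a set of trials and act as every
fitting target:

* **trial length** — segments per trial, binned 1–30 with longer trials
  pooled into the top bin;
* **vestibule visits** — share of visits per vestibule;
* **segment size** — share per signed size, −12…+12 without 0;
* **serial bout length** — a bout is a maximal run of consecutive
  one-door segments in a single direction (runs of +1 and runs of −1 are
  distinct); lengths are binned 1–15 with overflow pooled.

The caps are configurable; pooled overflow conserves probability mass.

## Three stochastic strategy processes

Each process draws the next vestibule given the current one and is run
recursively until the goal is reached:

* **random** — uniform over the other 23 vestibules. A repeat of the
  current vestibule would create a zero-size segment, which the segment
  algebra excludes, so the draw conditions on leaving; this mirrors the
  redraw rule the two other processes use.
* **spatial** — goal-directed: probability proportional to
  $\exp(-d/\tau)$, where $d$ is the door distance to the goal and
  $\tau = 2$ door-intervals; redrawn while the current vestibule is
  selected. Sampling is exact categorical sampling from the renormalized
  weights rather than an integer-quantized cumulative-sum scheme — the
  quantized scheme converges to this in the fine-grained limit, and exact
  sampling removes the quantization bias.
* **serial** — consecutive-hole visiting: the signed step is
  $\mathrm{round}(c + \sigma z)$ with $z$ standard normal, using
  $c = 1.2, \sigma = 1.2$ clockwise and $c = -2, \sigma = 1.5$
  counterclockwise. In the unified process the direction is drawn first,
  clockwise with probability 0.8. The magnitude is redrawn until it is
  nonzero and agrees with the drawn direction (the continuous draw leaves
  both the integer conversion and the mismatched-sign case open; rounding
  plus sign-conditioned resampling keeps the two directed processes exact
  mirror halves of the unified one). The entire draw is redone in the
  practically unreachable case where the step wraps the full circle.

All three processes therefore share the invariant that consecutive visits
never repeat, so every segment has magnitude 1–12.

## The mixture model and its grid-search estimator

The mixture model alternates two steps: draw a strategy from percentages
$(P_\mathrm{random}, P_\mathrm{serial}, P_\mathrm{spatial})$, then let that
strategy's process generate the next $N$ segments; the trial stops the
moment the goal is visited. $N$ — the *strategy persistence* — is the
number of segments generated under one strategy before the strategy is
redrawn.

`fit_mixture()` is a pure simulation-based estimator, deliberately matching
the exhaustive search design rather than a likelihood method: for every
triple on the percent simplex (step 2 by default) it simulates the model on
the experimental start schedule (same mice, trials, and start positions),
summarizes, and computes the mean squared error against the target
distributions, pooling all bins of all four distributions with equal
weight. Equal bin weight is the plainest reading of a pooled mean squared
error; the component set is an argument (`components`) for sensitivity
analyses. Each grid point is re-simulated `repetitions = 10` times; the
surfaces are averaged *before* taking the arg-minimum (the alternative —
averaging the per-repetition arg-minima — is available as
`average = "argmin"`; surface averaging gives a smoother, deterministic
landscape). Exact ties on the averaged surface resolve toward larger
$P_\mathrm{spatial}$, then larger $P_\mathrm{serial}$ — ties are vanishingly
rare with continuous errors, but the rule makes the estimator a function.

`scan_n()` repeats the whole grid search for $N = 1 \ldots 15$ and selects
the $N$ with the smallest averaged minimal error. Two properties of this
scan are worth knowing. First, the error-by-$N$ profile is intrinsically
shallow beyond the mean trial length: once blocks outlast most trials,
increasing $N$ barely changes the generated distributions. Second, at small
sample sizes (a few hundred trials) the sampling noise of the target and of
the simulations is of the same order as the profile's curvature around its
minimum, so the arg-minimum can wander among neighbouring $N$ values from
seed to seed; parameter-recovery runs at a few hundred trials recover the
generating $N$ only approximately, and recovery sharpens with more trials.
The package reports the full profile (`error_by_n`) precisely so users can
judge the flatness rather than trust the arg-minimum alone.

## The Markov-chain model and its genetic-algorithm estimator

The Markov model replaces block persistence with per-segment strategy
transitions over four states — random, serial clockwise, serial
counterclockwise, spatial (the two serial directions become distinct
states, each using the direction-fixed serial draw). Its parameters form a
5×4 row-stochastic matrix: the first row is the initial-strategy
distribution, rows 2–5 the transition rows. The state ordering above is
fixed throughout the package.

`fit_markov()` estimates the matrix with a genetic algorithm: a population
(default 500) of candidate matrices, each scored by simulating the model on
the start schedule and taking the mean squared error of the objective
distributions — by default the per-segment-index segment-size and
vestibule distributions for the first 10 segments plus the pooled trial
length and serial bout distributions. The better half survives; the other
half is refilled by mutation (uniform noise on (−0.1, 0.1) per element,
then clamping negatives to zero and renormalizing rows, with an all-zero
row falling back to uniform) on odd generations and by row-wise crossover
of elite pairs on even generations. Initial individuals have flat-Dirichlet
rows. The fitted matrix is the renormalized elementwise average of the
final elite. Fitness is one fresh simulated dataset per individual per
generation by default — resampling every generation keeps the algorithm
from overfitting a single noise draw; `freeze_eval = TRUE` instead
evaluates every individual under one frozen simulation seed, making
fitness a deterministic function of the individual (useful for testing:
elitism then guarantees a non-increasing best error). Elites are re-scored
each generation by default; `reevaluate_elite = FALSE` carries cached
fitness instead.

A caution on identifiability, which the package's recovery tests make
concrete: the objective distributions are (almost entirely) per-index
*marginals* of the latent strategy sequence. The initial-strategy row is
pinned directly by the first-segment distributions and recovers well. The
transition rows, in contrast, enter only through the marginal occupancy
flow $p_{k+1} = p_k T$ (plus serial run statistics), an ill-conditioned
inversion because the occupancy sequence approaches its stationary point
within a few segments. Matrices differing substantially in individual
transition entries can generate objective distributions that differ by
less than the simulation noise at realistic sample sizes, so the genetic
algorithm converges reliably in *error* while the recovered transition
entries scatter along the flat directions. Consequently entry-wise
agreement with a generating matrix should be expected for the initial row
and the dominant self-transitions, not uniformly for all twenty entries;
the spread across `repetitions` of the algorithm (reported in `per_run`)
is the honest uncertainty statement.

## Rule-based trial classifier

For comparison with the classic trial-wise taxonomy, `classify_trial()`
labels a complete trial *serial* if the goal was reached via a terminal
direction-pure bout of at least 3 unit segments, else *spatial* if it has
fewer than 3 visits, else *random*. The published clauses leave two edges
open; the package tests serial first (a three-visit all-serial trial is
serial, not spatial) and labels non-serial trials of exactly three visits
random, so the three labels partition all complete trials.

## Synthetic data generator

`experiment_plan()` + `generate_dataset()` emulate the study design: 19
mice (10 male, 9 female), 10 trials per day, 19 days, one random start
sequence per day shared by all mice, starts at least 2 door-intervals from
the goal. Generating parameters can be a single mixture or Markov
parameter set or one per day; the default is a mixture with the published
early-acquisition weights (58.2/28.4/13.4 random/serial/spatial) and
persistence 6. Every generated segment carries its ground-truth strategy
label, which is what makes parameter recovery testable end to end.

`synthesize_xy_trajectory()` renders a visit sequence as a 25 Hz xy path:
a radial excursion 2 cm beyond the 47.5 cm visit-detection radius at each
visited vestibule, arc travel between vestibules at 0.9 × that radius in
the direction of the signed segment, constant 20 cm/s speed, and optional
Gaussian jitter (default SD 0.5 cm). It is a fixture generator with
unambiguous threshold crossings, not a biomechanical model: real
trajectories meander, vary speed, and cross the arena interior, so exact
round-trip recovery on these fixtures validates the segmenter's logic, not
its robustness to messy real paths. Visit detection assigns each
above-threshold excursion to the nearest 15° sector center by mean angle
and merges consecutive same-vestibule events unless the trajectory between
them retreats more than 3 cm below the threshold — a debounce against
jitter splitting one physical visit, far shallower than any genuine return
toward the arena center.

## Numerical and scale choices

* Antipodal (12-door) displacements are reported as +12: sequence data
  cannot reveal the actual travel direction, and a deterministic tie-break
  keeps segment algebra reproducible. The trajectory segmenter is free of
  the issue because it observes the travel direction.
* Simulated trials are hard-capped at 1000 segments (`max_steps_per_trial`);
  a capped trial is flagged truncated and excluded from summaries. Under
  pure-random dynamics the mean trial length is 23 segments, so the cap is
  ~40 standard deviations out; `generate_dataset()` errors if more than 1%
  of trials truncate, which indicates a misconfigured guard.
* Grid fits in the package's own test and acceptance runs use 190–600
  trial schedules, grid increments of 2–10 and 10 repetitions; the
  genetic-algorithm recovery runs use population 100 over 100 generations
  on 1900-trial schedules. These sizes were chosen so the full
  verification suite completes on a single CPU while remaining at the
  experiment's own scale (19 mice × 10 trials per fitted day).
* All randomness flows through R's global RNG: callers `set.seed()` once
  and every generator, fit and simulation is bit-reproducible.

## Known limitations

* The estimators are simulation-based; their precision is bounded by
  sampling noise of both target and simulated distributions. The
  `error_by_n` profile and the GA `per_run` spread quantify this.
* The mixture and Markov estimators assume the start schedule used for
  simulation matches the one behind the target data; fitting with a
  mismatched schedule biases the vestibule-visit component.
* Serial-bout semantics are direction-pure by design; analyses that prefer
  sign-agnostic bouts can recompute from `segments_from_visits()`.
* The trial classifier reproduces a coarse published taxonomy for
  comparison purposes and is not a competitor to the model-based
  estimators.
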