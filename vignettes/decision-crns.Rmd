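---
title: "Probabilistic decision-making and operant conditioning in stochastic CRNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic decision-making and operant conditioning in stochastic CRNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnlearn)
```

# The model

`crnlearn` simulates abstract chemical reaction networks, interpreted
stochastically over integer molecule counts, that implement a
population-level probabilistic choice.  The model rests on three
assumptions worth stating explicitly:

* **well-mixed, count-space kinetics** — every reaction fires with a
  propensity equal to its stochastic rate constant times the number of
  distinct reactant combinations; there is no volume or concentration
  anywhere, and time is in abstract units;
* **mass conservation in the decision core** — the decision species X,
  Y(, Z, ...) and the undecided intermediate B interconvert but are never
  created or destroyed, and the weight species are pure catalysts whose
  total is likewise conserved, so the decision population and the
  probability "budget" are both fixed resources;
* **an external, black-box environment** — stimulus application/removal
  and Good/Bad feedback are exogenous events injected at scheduled times,
  not chemistry; the CRN's reactions are identical whatever the
  environment's strategy is.

## Module anatomy

The motif library composes a decision system from independent reaction
modules, for any number `k >= 2` of states:

| module | reactions | rate constant (default) |
|---|---|---|
| entropy generation | `A <-> C` for every state pair | `kNoise = 1` |
| approximate majority (AM) | `A + C + S -> B + B + S`; `B + A + S -> A + A + S` | `kAM = 1` |
| probability weighting | `B + WA -> A + WA` | `kBias = 30` |
| feedback processing | `Good + A + WC -> A + WA`; `Bad + A + WA -> A + WC`; `Good/Bad -> 0` | `kFB = 1`, `kFBDeg = 1` |
| response generation | `A -> A + RA`; `A + RC -> A`; `RA -> 0` | all 1 |
| weight resetting | `WA <-> WC` | `kWeightReset = 0.003` |
| decision erasure | `A -> B` | `kErase = 1` |

Every AM reaction is catalyzed by the stimulus S, so the consensus drive
only exists while a stimulus is present; the entropy module then relaxes
the population back to an even fluctuating split, erasing the previous
decision.  The bias reactions are *not* stimulus-catalyzed in the main
design — B is absent without stimulus, so gating them would be redundant —
except in the decision-erasure variant, where states drain into B between
stimuli and ungated bias reactions would immediately convert them back.

For `k > 2` the entropy module uses the complete interconversion graph
(every ordered state pair) at a single `kNoise`.  This is the simplest
scheme whose symmetric equilibrium is an even split across all k states;
a cycle topology would equilibrate to the same marginal distribution but
mixes more slowly, and nothing in the reference behaviors constrains the
choice, so the complete graph is used throughout.  Negative feedback
redistributes weight uniformly: one `Bad + A + WA -> A + WC` reaction per
alternative `C`, all at the same rate, encoding a no-assumptions prior
over where probability mass should go when a choice is punished.

`kErase` (decision erasure) defaults to 1, consistent with the unit rate
constants of every other non-tuning module; the erasure variant's
qualitative behavior (all mass in B without stimulus, reproducible
decisions with stimulus) does not depend on its exact value.

## Why the probabilities are tunable

With the stimulus off, X fluctuates binomially around N/2.  Stimulus
onset freezes a random initial margin, which AM then amplifies to
consensus.  The weight catalysts tilt the amplification: B produced by
annihilation is recruited at rate `kAM * B * A * S` by state A but also at
`kBias * B * WA` by its weight, so a 60:40 weight split at `kBias = 30`
lets the initially-losing side win often enough to shift the choice
probability from 0.50 to about 0.70.  The full map from weight fraction
`WX/(WX+WY)` to P(X) is the **transfer curve**; it is estimated by
Monte-Carlo (`transfer_curve()`) on a 25-point grid joined by straight
lines and doubles as the calibration that converts weight trajectories
into probability trajectories during conditioning experiments
(`calibrate_probability()`).

# The simulator

`simulate_crn()` implements the exact Gillespie direct method with three
deliberate semantic choices:

* **Perturbations discard and resample.**  A scheduled perturbation (e.g.
  "set Stimulus to 100 at t = 0.45") is applied at its exact time; the
  tentative reaction that would have fired beyond it is discarded and the
  waiting time resampled from the updated propensities.  By memorylessness
  of the exponential this is exact, not an approximation.
* **Sampling is right-continuous.**  The state recorded at sample time t
  reflects every reaction and perturbation with occurrence time `<= t`;
  the horizon sample is always emitted.  Sampling never consumes
  randomness, so the sample grid can be changed without disturbing the
  event sequence.
* **Two independent random streams.**  The CRN event sequence draws from
  a stream seeded by the trace seed; environment coin flips (probabilistic
  feedback) draw from a second stream derived from it.  Changing a
  feedback policy therefore cannot perturb the chemistry before the first
  differing injection — a property the test suite checks directly.
  Per-trace seeds derive deterministically from `(master_seed, index)`,
  so ensembles are reproducible as a whole and per trace.

Counts are clamped at zero on negative `add_count()` perturbations (none
of the reference experiments use them, but the contract is fail-safe), and
a zero total propensity simply idles the system until the next
perturbation or the horizon.

The inner loop is compiled (Rcpp) but consumes R's own RNG, which keeps
`set.seed()` reproducibility and makes two exactness properties testable:
two events per firing means rate rescaling yields *bit-identical* event
sequences with rescaled times, and the simulator can be compared against
a brute-force chemical master equation solution (state-space enumeration
plus matrix exponential) on a 4-molecule decision system, where the
total-variation distance stays within Monte-Carlo noise.

# The environment

`compile_environment()` turns a declarative environment into simulator
perturbations.  Each stimulus cycle contributes three events: set the
stimulus at the window start, attempt feedback at the window **midpoint**,
and zero the stimulus at the window end.  Midpoint timing guarantees
feedback always arrives while the stimulus is present, which matters
because the feedback reactions are catalyzed by a *state* species —
injected while the population is dispersed, Good/Bad would reallocate
weights unpredictably.  Detection is thresholded (`>= 90` of 100 state
molecules; `>= 40` for the noisier response species): if no species — or
more than one — qualifies at the midpoint, no feedback is given that
cycle.  Policies are time-piecewise maps from detected labels to
`(pGood, pBad, amount)`, which covers deterministic environments
(probabilities 0/1), probabilistic ones (2/3 / 1/3), and dynamic ones
(pieces switching at a set time).

The conditioning experiments use 4-on/6-off cycles with a 100-molecule
stimulus.  The binary conditioning runs are specified by their cycle
count and horizon (20 cycles to t = 200; 50 cycles with a policy flip at
t = 200), which this timing matches exactly, placing the flip on a cycle
boundary; the ternary response-based experiment states the same timing
explicitly.

# Experiments and chosen problem sizes

All procedures take a `master_seed` and are deterministic given it.

* `transfer_curve()` / `decision_probability()` — 0.5-unit traces, 100
  stimulus molecules at t = 0.45, classification at t = 0.475 (midway
  between stimulus and horizon) by the `>= 90` rule.  Traces that end
  undecided (neither state at threshold) are counted in the estimator's
  denominator and reported separately: this is the conservative choice,
  and it makes the estimator auditable since `p_x + p_y +
  undecided-fraction = 1` exactly.
* `first_passage_reset()` — first time X relaxes from full consensus to
  N/2 under entropy generation alone; the summary reports the 95th
  percentile as the operational "reset time", the quantile used when
  asserting that a 6-unit gap suffices at `kNoise = 1`.
* `sequential_decisions()` — many decisions along one trajectory, with a
  configurable relaxation gap (default 6 units, i.e. at or above the
  reset time; shorter gaps trigger a memory-effect warning).  Each cycle
  is classified at its stimulus-window midpoint, generalizing the
  single-decision classification time.
* `conditioning_run()` / `conditioning_ensemble()` /
  `ensemble_probability()` — full environment-coupled runs with per-cycle
  feedback logs and calibrated P(X) traces; ensemble statistics are
  pointwise means and standard deviations across replicates.
* `crossing_time()` — the adaptation lag after a policy flip, measured on
  the ensemble-*mean* calibrated trace (the quantity that is meaningful
  "on average"), interpolating linearly between the two samples that
  straddle the 0.5 level.

Monte-Carlo sizes were fixed as follows: 10^4 traces per switching
probability (binomial standard error about 0.005, an order of magnitude
below the effects of interest), 2 x 10^3 traces per calibration-curve grid
point (SE about 0.011, negligible for a curve used only as a monotone
interpolant), 50 replicates for conditioning ensembles, and 10^4 traces
for first-passage distributions.  The forgetting configuration (`fig5b`)
keeps the decision population at 100 molecules while using 500+500
weights, and is calibrated against a 1000-weight transfer curve at
`kBias = 3`, matching its weight pool.

# What the generator does and does not emulate

The canned configurations generate exactly the idealized study
conditions: square stimulus waveforms, perfectly timed midpoint feedback,
threshold detection with no sensor noise, and an environment with no
memory across cycles.  Passing tests therefore demonstrate the *design's*
properties — tunability, conditioning, adaptation, forgetting — under
clean digital signaling.  They do not demonstrate robustness to graded
stimulus waveforms, mistimed or missing feedback, crosstalk with other
chemistry, or enzymatic degradation of the decision species, none of
which the conservation-based core models.

# Known limitations

* The direct method is exact but serial per trace; systems far beyond
  ~10^3 molecules or rate constants far above ~10^2 would call for
  tau-leaping or hybrid schemes, which are out of scope.
* Calibrated probability traces are defined for binary systems (one
  weight fraction); k-way conditioning runs log feedback and weights but
  are not converted to k-dimensional probability vectors.
* The environment compiler covers periodic schedules only; aperiodic
  schedules can still be expressed directly as perturbation lists.
* Simultaneous perturbations at the same instant are applied in list
  order; the compiler never generates them.
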