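# crnlearn

Stochastic chemical reaction networks (CRNs) that make **population-level
probabilistic decisions** and **learn from environmental feedback**.

`crnlearn` is aimed at molecular programmers and systems/synthetic
biologists studying how a well-mixed population of ~100–1000 abstract
molecules can (i) commit, as a whole, to one of k responses with a tunable
probability, and (ii) adjust those probabilities over time through operant
conditioning — reinforcement delivered by an external environment based on
the decisions the chemistry itself has taken.

## The model

The core motif is a stimulus-gated **approximate-majority (AM)** consensus
network over k competing state species (X, Y, …) with an undecided
intermediate B, wrapped by four ideas:

```
entropy generation    X <-> Y                                @ kNoise
approximate majority  X + Y + S -> B + B + S                 @ kAM
                      B + X + S -> X + X + S                 @ kAM
                      B + Y + S -> Y + Y + S                 @ kAM
probability weighting B + WX -> X + WX,  B + WY -> Y + WY    @ kBias
feedback processing   Good + X + WY -> X + WX  (etc.)        @ kFB
                      Good -> 0,  Bad -> 0                   @ kFBDeg
```

* Between decisions the slow reversible reaction (`kNoise`) randomizes
  which state holds the majority, so the pre-decision state fluctuates
  around an even split.
* When the catalytic stimulus S is introduced, the AM reactions drive the
  entire population into whichever state happens to lead — a coordinated,
  random, population-wide choice.
* Conserved weight catalysts WX/WY bias the recruitment of B, so the
  choice probability becomes a smooth, monotone function of the weight
  fraction WX/(WX+WY): the **transfer curve**, the system's tuning knob
  and its calibration from weights to probabilities.
* Good/Bad feedback species, injected by the environment after observing
  a decision, convert weights between types (conserving their total), so
  reinforcement reshapes future decision probabilities — operant
  conditioning with no hard-coded environment model inside the CRN.

All simulation is exact Gillespie (direct method) over integer molecule
counts, with runtime perturbations for stimulus scheduling and
state-dependent feedback, and fully reproducible seeding.

## Worked example

Build the weighted binary decision system and estimate its switching
probability (weights 60/40):

```r
library(crnlearn)

spec <- decision_system_spec(initial_counts = c(X = 50, Y = 50, WX = 60, WY = 40))
net  <- build_decision_system(spec)
net
#> <crn_network: 6 species, 7 reactions>
#> X -> Y @ 1
#> Y -> X @ 1
#> Stimulus + X + Y -> B + B + Stimulus @ 1
#> B + Stimulus + X -> Stimulus + X + X @ 1
#> B + Stimulus + Y -> Stimulus + Y + Y @ 1
#> B + WX -> WX + X @ 30
#> B + WY -> WY + Y @ 30

decision_probability(wx = 60, wy = 40, n_traces = 10000, master_seed = 1)$p_x
#> [1] 0.7016
```

A 60:40 weight split translates into a ~70:30 decision: each of the 10^4
traces ran the network for 0.5 time units, added 100 stimulus molecules at
t = 0.45, and was classified X when at least 90 of the 100 state molecules
were X at t = 0.475.

How long must the system rest between decisions?  The first-passage time
from full consensus back to the even split answers this:

```r
first_passage_reset(n_population = 100, kNoise = 1,
                    n_traces = 10000, master_seed = 1)
#> <first_passage_summary: n = 100, kNoise = 1, 10000 traces>
#>   mean 1.466; quantiles: 50% = 1.339, 90% = 2.167, 95% = 2.531, 99% = 3.401
```

so waiting ~6 time units between stimuli is ample at `kNoise = 1`.

Conditioning: run 20 stimulus/relaxation cycles in an environment that
rewards X-decisions with probability 2/3 (10 Good molecules) and punishes
them with probability 1/3 (10 Bad molecules), and vice versa for Y, then
read the decision probability off the kBias = 30 transfer curve:

```r
curve <- transfer_curve(kBias = 30, n_traces = 2000, master_seed = 101)
res   <- run_config(canned_config("fig3b"), seed = 5, curve = curve)
head(res$feedback_log, 4)
#>   cycle time detected response species delta
#> 1     1    2        Y     good    Good    10
#> 2     2   12        X     good    Good    10
#> 3     3   22        X     good    Good    10
#> 4     4   32        Y     good    Good    10

tail(res$trajectory$counts[, c("WX", "WY")], 1)   # weights after 20 cycles
#>      WX WY
#>     100  0
tail(res$p_x, 1)                                  # calibrated P(X)
#> [1] 0.996
```

The environment's asymmetric reinforcement walks the conserved weight pool
toward WX, conditioning the circuit to choose X nearly always.

`canned_config()` provides ready-made configurations for all the library's
reference experiments (binary/ternary decisions, dynamic environments,
response-species conditioning, weight forgetting); a thin command-line
front end is installed under `inst/cli/crnlearn`.

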