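# Reaction modules for population-level probabilistic decision-making and
# their composition into complete k-way decision/conditioning systems.
#
# The architecture: a slow reversible interconversion of the k state species
# keeps the majority random before a decision ("entropy generation"); a
# stimulus-catalyzed approximate-majority (AM) module drives the whole
# population to a consensus of whichever state leads when the stimulus
# arrives; conserved weight species bias the recruitment of the undecided
# intermediate B and thereby set the decision probabilities; Good/Bad
# feedback reactions convert weights between types, implementing operant
# conditioning; optional response, weight-resetting and decision-erasure
# modules extend the basic system.

.check_states <- function(states) {
  if (length(states) < 2L) stop("need at least 2 state species", call. = FALSE)
  .check_species_name(states)
  if (anyDuplicated(states)) stop("state names must be distinct", call. = FALSE)
  states
}

#' Entropy-generation module
#'
#' A reversible unimolecular interconversion between every unordered pair of
#' state species (the complete interconversion graph), all at rate `kNoise`.
#' In the absence of stimulus this randomizes which state holds the
#' majority, fluctuating around an even split.
#'
#' @param states Character vector of k >= 2 state species.
#' @param kNoise Interconversion rate constant (default 1).
#' @return A `crn_network` of `k*(k-1)` reactions.
#' @export
entropy_module <- function(states, kNoise = 1) {
  .check_states(states)
  rxns <- list()
  for (i in seq_along(states)) {
    for (j in seq_along(states)) {
      if (i != j) {
        rxns[[length(rxns) + 1L]] <-
          reaction(states[[i]], states[[j]], kNoise)
      }
    }
  }
  reaction_network(rxns)
}

#' Stimulus-catalyzed approximate-majority module
#'
#' For every unordered state pair `{A, C}`: `A + C + Stimulus -> B + B +
#' Stimulus`, and for every state `A`: `B + A + Stimulus -> A + A +
#' Stimulus`, all at `kAM`.  Two opposing states annihilate into the
#' undecided intermediate `B`, which is catalytically recruited back to
#' either side; with stimulus present this drives the population to a
#' consensus of whichever state is in the majority.  Every reaction
#' conserves the state total plus `B`.
#'
#' @inheritParams entropy_module
#' @param intermediate Name of the undecided intermediate (default `"B"`).
#' @param stimulus Name of the catalytic stimulus species.
#' @param kAM Rate constant (default 1).
#' @return A `crn_network` of `k*(k-1)/2 + k` reactions.
#' @export
am_module <- function(states, intermediate = "B", stimulus = "Stimulus",
                      kAM = 1) {
  .check_states(states)
  if (intermediate %in% states || stimulus %in% states ||
      intermediate == stimulus) {
    stop("intermediate and stimulus names must differ from the states",
         call. = FALSE)
  }
  rxns <- list()
  k <- length(states)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      rxns[[length(rxns) + 1L]] <- reaction(
        c(states[[i]], states[[j]], stimulus),
        c(intermediate, intermediate, stimulus), kAM)
    }
  }
  for (a in states) {
    rxns[[length(rxns) + 1L]] <- reaction(
      c(intermediate, a, stimulus), c(a, a, stimulus), kAM)
  }
  reaction_network(rxns)
}

#' Probability-weighting (bias) module
#'
#' Each weight species catalytically recruits the undecided intermediate to
#' its own state: `B + WA -> A + WA` at `kBias`.  Weights are conserved
#' catalysts, so the relative weight counts set the decision probabilities.
#' With `stimulus_catalyzed = TRUE` (required by the decision-erasure
#' variant) the stimulus is an additional catalyst on every bias reaction.
#'
#' @inheritParams am_module
#' @param weights Character vector of weight species, aligned positionally
#'   with `states`.
#' @param kBias Rate constant (default 30).
#' @param stimulus_catalyzed Add the stimulus as catalyst.
#' @return A `crn_network` of k reactions.
#' @export
bias_module <- function(states, weights, intermediate = "B", kBias = 30,
                        stimulus_catalyzed = FALSE, stimulus = "Stimulus") {
  .check_states(states)
  if (length(weights) != length(states)) {
    stop("one weight species per state required", call. = FALSE)
  }
  rxns <- lapply(seq_along(states), function(i) {
    if (stimulus_catalyzed) {
      reaction(c(intermediate, weights[[i]], stimulus),
               c(states[[i]], weights[[i]], stimulus), kBias)
    } else {
      reaction(c(intermediate, weights[[i]]),
               c(states[[i]], weights[[i]]), kBias)
    }
  })
  reaction_network(rxns)
}

#' Feedback-processing (operant conditioning) module
#'
#' Trimolecular reactions in which the Good and Bad feedback species act in
#' concert with a state/weight pair, converting one weight type into
#' another while conserving the weight total:
#' * `Good + A + WC -> A + WA` for every state `A` and mismatched weight
#'   `WC` (positive reinforcement: weights are pulled toward the current
#'   state);
#' * `Bad + A + WA -> A + WC` for every non-matching `C`, one reaction per
#'   target, so negative reinforcement redistributes weight away from the
#'   current state uniformly (no inherent bias in reallocation);
#' * `Good -> 0` and `Bad -> 0` at `kFBDeg`, draining feedback that finds
#'   no state/weight pair to act on so it cannot linger into later rounds.
#'
#' @inheritParams bias_module
#' @param good,bad Feedback species names.
#' @param kFB Conversion rate constant (default 1).
#' @param kFBDeg Feedback degradation rate constant (default 1).
#' @return A `crn_network` of `2*k*(k-1) + 2` reactions.
#' @export
feedback_module <- function(states, weights, good = "Good", bad = "Bad",
                            kFB = 1, kFBDeg = 1) {
  .check_states(states)
  if (length(weights) != length(states)) {
    stop("one weight species per state required", call. = FALSE)
  }
  rxns <- list()
  k <- length(states)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        # Good: mismatched weight converted to match the current state
        rxns[[length(rxns) + 1L]] <- reaction(
          c(good, states[[i]], weights[[j]]),
          c(states[[i]], weights[[i]]), kFB)
      }
    }
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        # Bad: matching weight converted to each non-matching weight
        rxns[[length(rxns) + 1L]] <- reaction(
          c(bad, states[[i]], weights[[i]]),
          c(states[[i]], weights[[j]]), kFB)
      }
    }
  }
  rxns[[length(rxns) + 1L]] <- reaction(good, character(0), kFBDeg)
  rxns[[length(rxns) + 1L]] <- reaction(bad, character(0), kFBDeg)
  reaction_network(rxns)
}

#' Response-generation module
#'
#' Links each decision state to a distinct downstream response species:
#' `A -> A + RA` at `kResponse` (catalyzed generation), `A + RC -> A` at
#' `kResponseRepression` for every other response (cross-inhibition), and
#' `RA -> 0` at `kResponseDecay`.  With all states at comparable counts the
#' responses stay low; once one state dominates, its response goes high
#' while the others are repressed.
#'
#' @inheritParams bias_module
#' @param responses Character vector of response species, aligned with
#'   `states`.
#' @param kResponse,kResponseRepression,kResponseDecay Rate constants
#'   (defaults 1).
#' @return A `crn_network` of `k + k*(k-1) + k` reactions.
#' @export
response_module <- function(states, responses, kResponse = 1,
                            kResponseRepression = 1, kResponseDecay = 1) {
  .check_states(states)
  if (length(responses) != length(states)) {
    stop("one response species per state required", call. = FALSE)
  }
  rxns <- list()
  k <- length(states)
  for (i in seq_len(k)) {
    rxns[[length(rxns) + 1L]] <- reaction(
      states[[i]], c(states[[i]], responses[[i]]), kResponse)
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        rxns[[length(rxns) + 1L]] <- reaction(
          c(states[[i]], responses[[j]]), states[[i]],
          kResponseRepression)
      }
    }
  }
  for (i in seq_len(k)) {
    rxns[[length(rxns) + 1L]] <- reaction(
      responses[[i]], character(0), kResponseDecay)
  }
  reaction_network(rxns)
}

#' Weight-resetting (forgetting) module
#'
#' Slow reversible interconversion between every unordered pair of weight
#' species at `kWeightReset`.  Without reinforcement the weights relax
#' toward the even split, so conditioning is gradually forgotten.
#'
#' @param weights Character vector of k >= 2 weight species.
#' @param kWeightReset Rate constant (default 0.003).
#' @return A `crn_network` of `k*(k-1)` reactions.
#' @export
weight_reset_module <- function(weights, kWeightReset = 0.003) {
  net <- entropy_module(weights, kNoise = kWeightReset)
  net
}

#' Decision-erasure module
#'
#' Converts every state species to the undecided intermediate at a constant
#' rate: `A -> B` at `kErase`.  Intended as a replacement for
#' [entropy_module()], combined with [am_module()] and a
#' stimulus-catalyzed [bias_module()]: without stimulus no B-consuming
#' reaction is active, so the whole population relaxes to a consensus of B
#' and every decision starts from the same blank state.
#'
#' @inheritParams am_module
#' @param kErase Rate constant (default 1).
#' @return A `crn_network` of k reactions.
#' @export
decision_erasure_module <- function(states, intermediate = "B", kErase = 1) {
  .check_states(states)
  rxns <- lapply(states, function(a) reaction(a, intermediate, kErase))
  reaction_network(rxns)
}

#' Specify a complete decision/conditioning system
#'
#' Collects names, rate constants and module toggles for
#' [build_decision_system()].  Defaults are the reference parameterization
#' of the binary decision system: `kNoise = 1`, `kAM = 1`, `kBias = 30`,
#' `kFB = 1`, `kFBDeg = 1`, `kResponse = kResponseRepression =
#' kResponseDecay = 1`, `kWeightReset = 0.003`, `kErase = 1`.
#'
#' @param states State species names (k >= 2).
#' @param weights Weight species names, aligned with `states` (default
#'   `paste0("W", states)`).
#' @param intermediate,stimulus Intermediate and stimulus names.
#' @param good,bad Feedback species names.
#' @param responses Optional response species names, aligned with `states`.
#' @param initial_counts Named integer vector of initial molecule counts.
#' @param kNoise,kAM,kBias,kFB,kFBDeg,kResponse,kResponseRepression,kResponseDecay,kWeightReset,kErase
#'   Rate constants.
#' @param feedback,response,weight_reset,decision_erasure Module toggles.
#'   `decision_erasure = TRUE` replaces the entropy module and makes the
#'   bias reactions stimulus-catalyzed.
#' @return An object of class `decision_system_spec`.
#' @export
decision_system_spec <- function(states = c("X", "Y"),
                                 weights = paste0("W", states),
                                 intermediate = "B",
                                 stimulus = "Stimulus",
                                 good = "Good", bad = "Bad",
                                 responses = NULL,
                                 initial_counts = c(X = 50, Y = 50,
                                                    WX = 50, WY = 50),
                                 kNoise = 1, kAM = 1, kBias = 30,
                                 kFB = 1, kFBDeg = 1,
                                 kResponse = 1, kResponseRepression = 1,
                                 kResponseDecay = 1,
                                 kWeightReset = 0.003, kErase = 1,
                                 feedback = FALSE, response = FALSE,
                                 weight_reset = FALSE,
                                 decision_erasure = FALSE) {
  .check_states(states)
  all_names <- c(states, weights, intermediate, stimulus,
                 if (feedback) c(good, bad), responses)
  if (anyDuplicated(all_names)) {
    stop("species names collide: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(weights) != length(states)) {
    stop("one weight species per state required", call. = FALSE)
  }
  if (!is.null(responses) && length(responses) != length(states)) {
    stop("one response species per state required", call. = FALSE)
  }
  structure(list(
    states = states, weights = weights, intermediate = intermediate,
    stimulus = stimulus, good = good, bad = bad, responses = responses,
    initial_counts = initial_counts,
    rates = list(kNoise = kNoise, kAM = kAM, kBias = kBias, kFB = kFB,
                 kFBDeg = kFBDeg, kResponse = kResponse,
                 kResponseRepression = kResponseRepression,
                 kResponseDecay = kResponseDecay,
                 kWeightReset = kWeightReset, kErase = kErase),
    modules = list(feedback = feedback, response = response,
                   weight_reset = weight_reset,
                   decision_erasure = decision_erasure)),
    class = "decision_system_spec")
}

#' Build a complete decision system from a spec
#'
#' Composes the selected modules in canonical order (entropy or erasure,
#' approximate majority, bias, feedback, response, weight reset) with the
#' spec's rate constants and validates the result.
#'
#' @param spec A [decision_system_spec()].
#' @return A `crn_network`.
#' @examples
#' net <- build_decision_system(decision_system_spec())
#' length(net$reactions)  # 7 for the basic binary system
#' @export
build_decision_system <- function(spec) {
  stopifnot(inherits(spec, "decision_system_spec"))
  r <- spec$rates
  parts <- list()
  if (spec$modules$decision_erasure) {
    parts[[length(parts) + 1L]] <-
      decision_erasure_module(spec$states, spec$intermediate, r$kErase)
  } else {
    parts[[length(parts) + 1L]] <- entropy_module(spec$states, r$kNoise)
  }
  parts[[length(parts) + 1L]] <-
    am_module(spec$states, spec$intermediate, spec$stimulus, r$kAM)
  parts[[length(parts) + 1L]] <-
    bias_module(spec$states, spec$weights, spec$intermediate, r$kBias,
                stimulus_catalyzed = spec$modules$decision_erasure,
                stimulus = spec$stimulus)
  if (spec$modules$feedback) {
    parts[[length(parts) + 1L]] <-
      feedback_module(spec$states, spec$weights, spec$good, spec$bad,
                      r$kFB, r$kFBDeg)
  }
  if (spec$modules$response) {
    if (is.null(spec$responses)) {
      stop("response module enabled but no response names given",
           call. = FALSE)
    }
    parts[[length(parts) + 1L]] <-
      response_module(spec$states, spec$responses, r$kResponse,
                      r$kResponseRepression, r$kResponseDecay)
  }
  if (spec$modules$weight_reset) {
    parts[[length(parts) + 1L]] <-
      weight_reset_module(spec$weights, r$kWeightReset)
  }
  do.call(c, parts)
}
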