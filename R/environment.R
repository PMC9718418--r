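# The external environment: periodic stimulus application/removal,
# thresholded state detection, and probabilistic/time-dependent feedback
# injection, compiled down to simulator perturbations.

#' Periodic stimulus schedule
#'
#' Cycle `c` (0-based) occupies `[c*(on+off), c*(on+off) + on)` with the
#' stimulus present: the stimulus count is set to `amount` at the window
#' start and set to zero at the window end (the stimulus is a catalyst, so
#' removal must be exogenous).
#'
#' @param n_cycles Number of stimulus/relaxation cycles (>= 0).
#' @param on_duration,off_duration Window durations (> 0).
#' @param amount Stimulus molecules injected per window.
#' @param stimulus Stimulus species name.
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(n_cycles, on_duration, off_duration, amount,
                              stimulus = "Stimulus") {
  stopifnot(n_cycles >= 0, amount >= 1)
  if (n_cycles > 0 && (on_duration <= 0 || off_duration <= 0)) {
    stop("stimulus windows must have positive on and off durations",
         call. = FALSE)
  }
  structure(list(n_cycles = as.integer(n_cycles),
                 on_duration = as.numeric(on_duration),
                 off_duration = as.numeric(off_duration),
                 amount = as.integer(amount),
                 stimulus = stimulus),
            class = "stimulus_schedule")
}

#' Thresholded state detection rule
#'
#' @param watched Named character vector mapping labels to species (an
#'   unnamed vector uses the species names as labels).
#' @param threshold Positive integer count threshold.
#' @return An object of class `detection_rule`.
#' @export
detection_rule <- function(watched, threshold) {
  stopifnot(threshold >= 1)
  if (is.null(names(watched)) || any(!nzchar(names(watched)))) {
    names(watched) <- watched
  }
  structure(list(watched = watched, threshold = as.integer(threshold)),
            class = "detection_rule")
}

#' Detect the current decision state
#'
#' Returns the unique label whose watched species count is at or above the
#' threshold; `NA` if none or more than one qualifies (at the thresholds
#' used here a tie is impossible for state species, and a tie among e.g.
#' response species yields no feedback rather than an arbitrary choice).
#'
#' @param counts Named count vector.
#' @param rule A [detection_rule()].
#' @return A label string, or `NA_character_`.
#' @examples
#' detect(c(X = 95, Y = 3, B = 2), detection_rule(c(X = "X", Y = "Y"), 90))
#' @export
detect <- function(counts, rule) {
  stopifnot(inherits(rule, "detection_rule"))
  missing <- setdiff(rule$watched, names(counts))
  if (length(missing)) {
    stop("watched species absent from state: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hit <- counts[rule$watched] >= rule$threshold
  if (sum(hit) == 1L) names(rule$watched)[hit] else NA_character_
}

#' Time-piecewise probabilistic feedback policy
#'
#' A policy is an ordered list of pieces; each piece starts at `from_time`
#' and maps detected labels to `(pGood, pBad, amount)`.  On each feedback
#' opportunity the environment injects `amount` molecules of the Good
#' species with probability `pGood`, of the Bad species with probability
#' `pBad`, and nothing otherwise; labels absent from the active piece
#' receive no feedback.
#'
#' @param ... Pieces, each a list with `from_time` (numeric) and `rules`
#'   (named list mapping label to a numeric vector `c(pGood, pBad,
#'   amount)`).
#' @return An object of class `feedback_policy`.
#' @examples
#' feedback_policy(
#'   list(from_time = 0,
#'        rules = list(X = c(2/3, 1/3, 10), Y = c(1/3, 2/3, 10))))
#' @export
feedback_policy <- function(...) {
  pieces <- list(...)
  if (length(pieces) == 1L && is.null(pieces[[1]]$from_time)) {
    pieces <- pieces[[1]]  # a plain list of pieces was passed
  }
  if (!length(pieces)) stop("policy needs at least one piece", call. = FALSE)
  from <- vapply(pieces, function(p) as.numeric(p$from_time), numeric(1))
  if (is.unsorted(from)) {
    stop("policy pieces must be in increasing from_time order", call. = FALSE)
  }
  for (p in pieces) {
    for (lab in names(p$rules)) {
      e <- p$rules[[lab]]
      if (length(e) != 3L || any(e[1:2] < 0) || e[[1]] + e[[2]] > 1 + 1e-12 ||
          e[[3]] < 1) {
        stop(sprintf(
          "policy entry for '%s' must be c(pGood, pBad, amount) with pGood + pBad <= 1 and amount >= 1",
          lab), call. = FALSE)
      }
    }
  }
  structure(list(pieces = pieces, from_times = from),
            class = "feedback_policy")
}

.active_piece <- function(policy, time) {
  i <- findInterval(time + 1e-12, policy$from_times)
  if (i < 1L) return(NULL)
  policy$pieces[[i]]
}

#' Sample an environmental feedback response
#'
#' @param label Detected label (possibly `NA`).
#' @param policy A [feedback_policy()].
#' @param time Query time (selects the active policy piece).
#' @param u A uniform(0,1) variate from the environment random stream.
#' @return `NULL` for no feedback, else `list(kind = "good"|"bad",
#'   amount = <int>)`.
#' @export
sample_feedback <- function(label, policy, time, u) {
  stopifnot(inherits(policy, "feedback_policy"))
  if (is.na(label)) return(NULL)
  piece <- .active_piece(policy, time)
  if (is.null(piece)) return(NULL)
  e <- piece$rules[[label]]
  if (is.null(e)) return(NULL)
  if (u < e[[1]]) {
    list(kind = "good", amount = as.integer(e[[3]]))
  } else if (u < e[[1]] + e[[2]]) {
    list(kind = "bad", amount = as.integer(e[[3]]))
  } else {
    NULL
  }
}

#' Full environment specification
#'
#' @param schedule A [stimulus_schedule()].
#' @param detection A [detection_rule()].
#' @param policy A [feedback_policy()].
#' @param good,bad Names of the feedback species injected for good/bad
#'   responses.
#' @return An object of class `environment_spec`.
#' @export
environment_spec <- function(schedule, detection, policy,
                             good = "Good", bad = "Bad") {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(detection, "detection_rule"),
            inherits(policy, "feedback_policy"))
  structure(list(schedule = schedule, detection = detection,
                 policy = policy, good = good, bad = bad),
            class = "environment_spec")
}

#' Compile an environment to simulator perturbations
#'
#' For each stimulus cycle: set the stimulus to `amount` at the window
#' start; at the window midpoint run detection, sample the policy, and
#' inject the chosen feedback species (if any); set the stimulus to zero at
#' the window end.  Feedback timing at the midpoint guarantees feedback
#' always arrives while the stimulus is present.
#'
#' @param spec An [environment_spec()].
#' @param horizon Simulation horizon; must cover the schedule.
#' @return Ordered list of [perturbation()] objects.
#' @export
compile_environment <- function(spec, horizon) {
  stopifnot(inherits(spec, "environment_spec"))
  sch <- spec$schedule
  extent <- sch$n_cycles * (sch$on_duration + sch$off_duration)
  if (sch$n_cycles > 0 && horizon < extent - sch$off_duration - 1e-9) {
    stop("horizon does not cover the stimulus schedule", call. = FALSE)
  }
  perts <- list()
  if (sch$n_cycles == 0L) return(perts)
  detection <- spec$detection
  policy <- spec$policy
  good <- spec$good
  bad <- spec$bad
  for (c in seq_len(sch$n_cycles) - 1L) {
    start <- c * (sch$on_duration + sch$off_duration)
    mid <- start + sch$on_duration / 2
    end <- start + sch$on_duration
    perts[[length(perts) + 1L]] <- perturbation(
      start, list(set_count(sch$stimulus, sch$amount)),
      sprintf("stimulus on (cycle %d)", c + 1L))
    cyc <- c + 1L
    perts[[length(perts) + 1L]] <- perturbation(
      mid,
      local({
        cycle_i <- cyc
        function(counts, time, u) {
          label <- detect(counts, detection)
          inj <- sample_feedback(label, policy, time, u)
          updates <- list()
          if (!is.null(inj)) {
            species <- if (inj$kind == "good") good else bad
            updates <- list(add_count(species, inj$amount))
          }
          attr(updates, "note") <- sprintf(
            "feedback cycle %d: detected=%s response=%s", cycle_i,
            if (is.na(label)) "none" else label,
            if (is.null(inj)) "none" else inj$kind)
          updates
        }
      }),
      sprintf("feedback cycle %d", cyc))
    perts[[length(perts) + 1L]] <- perturbation(
      end, list(set_count(sch$stimulus, 0)),
      sprintf("stimulus off (cycle %d)", c + 1L))
  }
  perts
}
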