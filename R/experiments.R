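# Reproducible experiment procedures: switching transfer curves,
# weight-to-probability calibration, first-passage reset times, sequential
# decisions, conditioning runs and ensemble statistics.

# Classify a sampled state: the unique state with count >= threshold, else
# "undecided".
.classify <- function(counts, states, threshold) {
  hit <- counts >= threshold
  if (sum(hit) == 1L) states[[which(hit)]] else "undecided"
}

#' Estimate a switching transfer curve
#'
#' Estimates the probability that the binary decision system converts the
#' whole population to state X, as a function of the weight fraction
#' `WX / (WX + WY)`, on a grid of `n_grid` evenly spaced fractions.  Each
#' trace follows the single-decision protocol: initialize `X = Y =
#' state_total/2` and `B = 0`, run for `horizon` time units, set the
#' stimulus to `stimulus_amount` at `stimulus_time`, and classify at
#' `classify_time` as the unique state with at least `threshold` molecules
#' ("undecided" otherwise; undecided traces count in the denominator and
#' are reported).
#'
#' Defaults are the reference protocol: 0.5-unit traces, 100 stimulus
#' molecules added at t = 0.45, classification at t = 0.475 with threshold
#' 90 in a 100-molecule system, 25 grid points.
#'
#' @param kBias Bias (probability-weighting) rate constant.
#' @param n_total_weights Total weight molecules `WX + WY`.
#' @param n_traces Traces per grid point (>= 100).
#' @param master_seed Integer master seed.
#' @param n_grid Number of evenly spaced weight fractions in `[0, 1]`.
#' @param state_total Total decision molecules (split evenly between X and
#'   Y at t = 0).
#' @param threshold Classification threshold (counts).
#' @param horizon,stimulus_time,classify_time,stimulus_amount Trace
#'   protocol parameters.
#' @param kNoise,kAM Remaining rate constants.
#' @return A `transfer_curve`: data frame with columns `fraction`, `wx`,
#'   `wy`, `p_x`, `n_traces`, `n_undecided`, and attributes `kBias`,
#'   `n_total_weights`.  Evaluation between grid points (see
#'   [calibrate_probability()]) is piecewise linear.
#' @export
transfer_curve <- function(kBias = 30, n_total_weights = 100,
                           n_traces = 10000, master_seed = 1,
                           n_grid = 25, state_total = 100, threshold = 90,
                           horizon = 0.5, stimulus_time = 0.45,
                           classify_time = 0.475, stimulus_amount = 100,
                           kNoise = 1, kAM = 1) {
  stopifnot(n_traces >= 100, n_grid >= 2)
  fractions <- seq(0, 1, length.out = n_grid)
  rows <- lapply(seq_along(fractions), function(i) {
    wx <- as.integer(round(fractions[[i]] * n_total_weights))
    est <- decision_probability(
      wx = wx, wy = n_total_weights - wx, n_traces = n_traces,
      master_seed = .derive_seed(master_seed, 500000 + i),
      kBias = kBias, kNoise = kNoise, kAM = kAM,
      state_total = state_total, threshold = threshold, horizon = horizon,
      stimulus_time = stimulus_time, classify_time = classify_time,
      stimulus_amount = stimulus_amount)
    data.frame(fraction = fractions[[i]], wx = wx,
               wy = n_total_weights - wx, p_x = est$p_x,
               n_traces = n_traces, n_undecided = est$n_undecided)
  })
  out <- do.call(rbind, rows)
  attr(out, "kBias") <- kBias
  attr(out, "n_total_weights") <- n_total_weights
  class(out) <- c("transfer_curve", class(out))
  out
}

#' Estimate a single-point switching probability
#'
#' The single-decision protocol of [transfer_curve()] at one weight
#' configuration: the probability that the population commits to X.
#'
#' @inheritParams transfer_curve
#' @param wx,wy Initial weight counts.
#' @return List with `p_x`, `p_y`, `n_undecided`, `n_traces`.
#' @examples
#' \donttest{
#' decision_probability(wx = 60, wy = 40, n_traces = 1000, master_seed = 1)
#' }
#' @export
decision_probability <- function(wx, wy, n_traces = 10000, master_seed = 1,
                                 kBias = 30, kNoise = 1, kAM = 1,
                                 state_total = 100, threshold = 90,
                                 horizon = 0.5, stimulus_time = 0.45,
                                 classify_time = 0.475,
                                 stimulus_amount = 100) {
  spec <- decision_system_spec(
    initial_counts = c(X = state_total %/% 2L,
                       Y = state_total - state_total %/% 2L,
                       WX = wx, WY = wy),
    kNoise = kNoise, kAM = kAM, kBias = kBias)
  net <- build_decision_system(spec)
  comp <- .compile_network(net)
  x0 <- .full_counts(net, spec$initial_counts)
  i_stim <- match(spec$stimulus, comp$species)
  i_x <- match("X", comp$species)
  i_y <- match("Y", comp$species)
  amount <- as.integer(stimulus_amount)
  pact <- list(function(x, u) { x[i_stim] <- amount; x })
  n_x <- 0L; n_y <- 0L
  for (i in seq_len(n_traces)) {
    m <- .run_sampled(comp, x0, horizon, stimulus_time, pact,
                      classify_time, seed = .derive_seed(master_seed, i))
    if (m[1L, i_x] >= threshold) n_x <- n_x + 1L
    else if (m[1L, i_y] >= threshold) n_y <- n_y + 1L
  }
  list(p_x = n_x / n_traces, p_y = n_y / n_traces,
       n_undecided = n_traces - n_x - n_y, n_traces = n_traces)
}

#' Convert weight counts to a decision probability
#'
#' Piecewise-linear interpolation of a [transfer_curve()] at the weight
#' fraction `wx / (wx + wy)`: the curve acts as a calibration from weight
#' counts to the probability of choosing X.
#'
#' @param wx,wy Weight counts (`wx + wy > 0`); vectors are interpolated
#'   elementwise.
#' @param curve A `transfer_curve` (or any data frame with `fraction` and
#'   `p_x` columns).
#' @return Interpolated probability (vector).
#' @export
calibrate_probability <- function(wx, wy, curve) {
  total <- wx + wy
  if (any(total <= 0)) stop("weight total must be positive", call. = FALSE)
  approx(curve$fraction, curve$p_x, xout = wx / total, rule = 2)$y
}

#' First-passage reset-time distribution
#'
#' Characterizes how long the system needs between decisions: starting from
#' a full consensus (`X = n_population`, `Y = 0`) with only the
#' entropy-generation reactions active, records per trace the first time
#' the X count falls to half the population, i.e. back to the even split
#' around which the pre-decision state fluctuates.
#'
#' @param n_population Even total state count.
#' @param kNoise Interconversion rate constant.
#' @param n_traces Number of traces.
#' @param master_seed Integer master seed.
#' @param horizon Per-trace cap on the search (the passage is recorded as
#'   `NA` if not reached; with `kNoise = 1` and `n_population = 100` the
#'   distribution is far inside the default).
#' @param start_x Initial X count (default the full population; a start at
#'   or below `n_population / 2` gives first-passage time 0).
#' @return A `first_passage_summary`: list with `times` (per-trace
#'   first-passage times), `mean`, and `quantiles` (50/90/95/99%).
#' @export
first_passage_reset <- function(n_population = 100, kNoise = 1,
                                n_traces = 10000, master_seed = 1,
                                horizon = 1000, start_x = n_population) {
  stopifnot(n_population %% 2 == 0, kNoise > 0, n_traces >= 1,
            start_x <= n_population)
  net <- entropy_module(c("X", "Y"), kNoise)
  comp <- .compile_network(net)
  i_x <- match("X", comp$species) - 1L  # 0-based for the kernel
  target <- n_population %/% 2L
  x0 <- c(as.integer(start_x), as.integer(n_population - start_x))
  old_rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
  }, add = TRUE)
  times <- vapply(seq_len(n_traces), function(i) {
    set.seed(.derive_seed(master_seed, i))
    res <- ssa_segment(comp$react_ptr, comp$react_idx, comp$react_mult,
                       comp$net_ptr, comp$net_idx, comp$net_delta,
                       comp$rates, x0, 0, horizon, numeric(0), FALSE,
                       i_x, target)
    if (res$stopped) res$stop_time else NA_real_
  }, numeric(1))
  structure(list(times = times,
                 mean = mean(times, na.rm = TRUE),
                 quantiles = quantile(times, c(0.5, 0.9, 0.95, 0.99),
                                      na.rm = TRUE, names = TRUE),
                 n_population = n_population, kNoise = kNoise),
            class = "first_passage_summary")
}

#' @export
print.first_passage_summary <- function(x, ...) {
  cat(sprintf(
    "<first_passage_summary: n = %d, kNoise = %g, %d traces>\n  mean %.3f;",
    x$n_population, x$kNoise, length(x$times), x$mean))
  cat(" quantiles:", paste(sprintf("%s = %.3f", names(x$quantiles),
                                   x$quantiles), collapse = ", "), "\n")
  invisible(x)
}

#' Sequential decisions along a single trajectory
#'
#' Repeated stimulus cycles on one long trace: each cycle applies the
#' stimulus for `on_duration` time units after a relaxation gap, and the
#' decision is classified at the stimulus-window midpoint.  With the gap at
#' or above the reset time the decisions are independent and the aggregate
#' probability matches the single-decision transfer-curve estimate.
#'
#' @inheritParams decision_probability
#' @param decisions_per_trace Stimulus cycles per trace.
#' @param on_duration Stimulus window length.
#' @param gap Relaxation time between windows (a warning is issued if below
#'   `reset_time`, since re-stimulation before the system has reset biases
#'   the next decision toward the previous state).
#' @param reset_time Reference reset time used for the warning (default 6,
#'   the 95th-percentile first-passage time at `kNoise = 1`).
#' @return List with `records` (data frame `trace`, `cycle`, `label`,
#'   `sample_time`), `p_x`, `p_y`, `n_undecided`, `n_decisions`.
#' @export
sequential_decisions <- function(wx, wy, n_traces = 100,
                                 decisions_per_trace = 100,
                                 master_seed = 1, kBias = 30, kNoise = 1,
                                 kAM = 1, state_total = 100, threshold = 90,
                                 on_duration = 0.05, gap = 6,
                                 stimulus_amount = 100, reset_time = 6) {
  stopifnot(n_traces >= 1, decisions_per_trace >= 1)
  if (gap < reset_time) {
    warning("inter-stimulus gap below the reset time: sequential decisions ",
            "will carry memory of the previous state", call. = FALSE)
  }
  spec <- decision_system_spec(
    initial_counts = c(X = state_total %/% 2L,
                       Y = state_total - state_total %/% 2L,
                       WX = wx, WY = wy),
    kNoise = kNoise, kAM = kAM, kBias = kBias)
  net <- build_decision_system(spec)
  comp <- .compile_network(net)
  x0 <- .full_counts(net, spec$initial_counts)
  i_stim <- match(spec$stimulus, comp$species)
  i_x <- match("X", comp$species)
  i_y <- match("Y", comp$species)
  amount <- as.integer(stimulus_amount)
  cycle_len <- gap + on_duration
  starts <- gap + (seq_len(decisions_per_trace) - 1L) * cycle_len
  mids <- starts + on_duration / 2
  ends <- starts + on_duration
  horizon <- ends[[length(ends)]]
  ptimes <- as.vector(rbind(starts, ends))
  on_fun <- function(x, u) { x[i_stim] <- amount; x }
  off_fun <- function(x, u) { x[i_stim] <- 0L; x }
  pacts <- rep(list(on_fun, off_fun), decisions_per_trace)
  recs <- vector("list", n_traces)
  for (tr in seq_len(n_traces)) {
    m <- .run_sampled(comp, x0, horizon, ptimes, pacts, mids,
                      seed = .derive_seed(master_seed, tr))
    labels <- vapply(seq_len(decisions_per_trace), function(cy) {
      .classify(c(m[cy, i_x], m[cy, i_y]), c("X", "Y"), threshold)
    }, character(1))
    recs[[tr]] <- data.frame(trace = tr,
                             cycle = seq_len(decisions_per_trace),
                             label = labels, sample_time = mids)
  }
  records <- do.call(rbind, recs)
  n_dec <- nrow(records)
  list(records = records,
       p_x = sum(records$label == "X") / n_dec,
       p_y = sum(records$label == "Y") / n_dec,
       n_undecided = sum(records$label == "undecided"),
       n_decisions = n_dec)
}

#' Run one operant-conditioning simulation
#'
#' Simulates a decision system under a compiled environment (periodic
#' stimulus, thresholded detection, probabilistic feedback), logging the
#' per-cycle detection/injection and, when a calibration curve is supplied,
#' attaching the calibrated decision-probability trace computed from the
#' weight counts at every sample.
#'
#' @param spec A [decision_system_spec()] (typically with
#'   `feedback = TRUE`).
#' @param env An [environment_spec()].
#' @param horizon Simulation end time.
#' @param seed Integer seed.
#' @param curve Optional [transfer_curve()] calibration; used to convert
#'   the first two weight species' counts into `P(first state)` (binary
#'   systems).
#' @param samples_per_unit Sampling rate.
#' @return A `conditioning_result`: list with `trajectory`,
#'   `feedback_log` (data frame `cycle`, `time`, `detected`, `response`,
#'   `species`, `delta`), and `p_x` (calibrated probability per sample, or
#'   `NULL` without a curve).
#' @export
conditioning_run <- function(spec, env, horizon, seed = 1, curve = NULL,
                             samples_per_unit = 100) {
  stopifnot(inherits(spec, "decision_system_spec"),
            inherits(env, "environment_spec"))
  net <- build_decision_system(spec)
  perts <- compile_environment(env, horizon)
  traj <- simulate_crn(net, spec$initial_counts, horizon, perts,
                       samples_per_unit = samples_per_unit, seed = seed)
  ev <- traj$events
  fb <- ev[grepl("^feedback cycle", ev$label), , drop = FALSE]
  feedback_log <- NULL
  if (nrow(fb)) {
    parse1 <- regmatches(
      fb$label,
      regexec("^feedback cycle (\\d+): detected=(\\S+) response=(\\S+)$",
              fb$label))
    feedback_log <- data.frame(
      cycle = vapply(parse1, function(p) as.integer(p[[2]]), integer(1)),
      time = fb$time,
      detected = vapply(parse1, `[[`, character(1), 3),
      response = vapply(parse1, `[[`, character(1), 4),
      species = fb$species,
      delta = fb$delta,
      stringsAsFactors = FALSE)
  }
  p_x <- NULL
  if (!is.null(curve)) {
    w1 <- traj$counts[, spec$weights[[1]]]
    w2 <- traj$counts[, spec$weights[[2]]]
    p_x <- calibrate_probability(w1, w2, curve)
  }
  structure(list(trajectory = traj, feedback_log = feedback_log, p_x = p_x,
                 spec = spec),
            class = "conditioning_result")
}

#' Run an ensemble of conditioning simulations
#'
#' @inheritParams conditioning_run
#' @param master_seed Integer master seed; per-replicate seeds derive from
#'   it deterministically.
#' @param n Number of replicates.
#' @return List of `conditioning_result` objects.
#' @export
conditioning_ensemble <- function(spec, env, horizon, master_seed = 1,
                                  n = 50, curve = NULL,
                                  samples_per_unit = 100) {
  lapply(seq_len(n), function(i) {
    conditioning_run(spec, env, horizon,
                     seed = .derive_seed(master_seed, i), curve = curve,
                     samples_per_unit = samples_per_unit)
  })
}

#' Ensemble mean and spread of calibrated decision probabilities
#'
#' @param results List of >= 2 `conditioning_result` objects on a common
#'   sample grid, each carrying a calibrated probability trace.
#' @return Data frame with columns `time`, `mean_p`, `sd_p`.
#' @export
ensemble_probability <- function(results) {
  if (length(results) < 2L) {
    stop("need at least 2 replicates for ensemble statistics",
         call. = FALSE)
  }
  times <- results[[1]]$trajectory$times
  for (r in results) {
    if (length(r$trajectory$times) != length(times) ||
        any(abs(r$trajectory$times - times) > 1e-9)) {
      stop("replicates are on different sample grids", call. = FALSE)
    }
    if (is.null(r$p_x)) {
      stop("all replicates need a calibrated probability trace ",
           "(pass a curve to conditioning_run)", call. = FALSE)
    }
  }
  p <- vapply(results, `[[`, numeric(length(times)), "p_x")
  data.frame(time = times,
             mean_p = rowMeans(p),
             sd_p = apply(p, 1, sd))
}

#' Time for a mean probability trace to cross a level
#'
#' Finds the first time after `flip_time` at which the trace crosses
#' `level` from the side it occupies at the flip, interpolating linearly
#' between samples, and returns the elapsed time since `flip_time` (`NA`
#' if the trace never crosses).
#'
#' @param times,p Sample times and mean probability values.
#' @param flip_time Reference time (e.g. when the feedback policy was
#'   inverted).
#' @param level Crossing level (default 0.5).
#' @return Duration after `flip_time`, or `NA`.
#' @export
crossing_time <- function(times, p, flip_time, level = 0.5) {
  keep <- times >= flip_time
  if (!any(keep)) stop("trace does not extend past flip_time", call. = FALSE)
  tt <- times[keep]
  vv <- p[keep]
  side <- sign(vv[[1]] - level)
  if (side == 0) return(0)
  crossed <- which(sign(vv - level) == -side)
  if (!length(crossed)) return(NA_real_)
  j <- crossed[[1]]
  # linear interpolation between the straddling samples
  t0 <- tt[[j - 1L]]; t1 <- tt[[j]]
  v0 <- vv[[j - 1L]]; v1 <- vv[[j]]
  tc <- t0 + (level - v0) / (v1 - v0) * (t1 - t0)
  tc - flip_time
}
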