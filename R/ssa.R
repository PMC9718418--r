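# Exact stochastic simulation (Gillespie direct method) with scheduled,
# state-dependent perturbations and fixed-rate trajectory sampling.

# Deterministic derivation of child seeds from a master seed.  Kept as pure
# 32-bit-safe double arithmetic so derived seeds are stable across platforms
# and always below 2^31.
.derive_seed <- function(master, index) {
  m <- 2147483629
  as.integer((abs(as.numeric(master)) %% m + 1000003 * (as.numeric(index) %% 1024) +
                7907 * (as.numeric(index) %/% 1024)) %% m)
}

# Environment (feedback coin-flip) stream is derived from the trace seed so
# that redefining a feedback policy never perturbs the CRN event sequence.
.env_seed <- function(seed) .derive_seed(seed, 999983)

#' Count update actions for perturbations
#'
#' `set_count` replaces a species count; `add_count` shifts it by `delta`
#' with the result clamped at zero.  Perturbation actions return lists of
#' these updates.
#'
#' @param species Species name.
#' @param value Non-negative replacement count.
#' @param delta Signed change in count.
#' @return An update object understood by [simulate_crn()].
#' @export
set_count <- function(species, value) {
  if (value < 0) stop("set_count value must be >= 0", call. = FALSE)
  list(op = "SET", species = species, value = as.integer(value))
}

#' @rdname set_count
#' @export
add_count <- function(species, delta) {
  list(op = "ADD", species = species, value = as.integer(delta))
}

#' Schedule a perturbation
#'
#' A perturbation applies an exogenous change to the molecule counts at an
#' exact simulation time.  `action` is called as `action(counts, time, u)`
#' where `counts` is the current named count vector and `u` is one uniform
#' variate from the environment random stream (independent of the CRN event
#' stream); it returns a list of [set_count()]/[add_count()] updates,
#' optionally with an attribute `note` (free text copied to the event log,
#' e.g. a detected state label).
#'
#' @param time Non-negative time at which to apply the action.
#' @param action Function `(counts, time, u) -> list of updates`, or a plain
#'   list of updates for state-independent perturbations.
#' @param label Free-text label recorded in the trajectory event log.
#' @return An object of class `crn_perturbation`.
#' @examples
#' perturbation(0.45, list(set_count("Stimulus", 100)), "stimulus on")
#' @export
perturbation <- function(time, action, label = "") {
  if (time < 0) stop("perturbation time must be >= 0", call. = FALSE)
  if (!is.function(action)) {
    updates <- action
    action <- function(counts, time, u) updates
  }
  structure(list(time = as.numeric(time), action = action,
                 label = as.character(label)),
            class = "crn_perturbation")
}

.apply_updates <- function(counts, updates) {
  applied <- list()
  for (up in updates) {
    if (is.null(up)) next
    s <- up$species
    if (!s %in% names(counts)) {
      stop("perturbation names unknown species: ", s, call. = FALSE)
    }
    before <- counts[[s]]
    if (up$op == "SET") {
      if (up$value < 0) stop("SET to negative count", call. = FALSE)
      counts[[s]] <- up$value
    } else if (up$op == "ADD") {
      counts[[s]] <- max(0L, before + up$value)
    } else {
      stop("unknown perturbation op: ", up$op, call. = FALSE)
    }
    applied[[length(applied) + 1L]] <-
      list(species = s, delta = counts[[s]] - before)
  }
  list(counts = counts, applied = applied)
}

#' Simulate a reaction network exactly
#'
#' Gillespie direct method: waiting times are exponential with rate equal to
#' the total propensity and the firing reaction is chosen proportionally to
#' the individual propensities.  Scheduled perturbations are applied at
#' their exact times; the tentative next reaction is discarded and resampled
#' afterwards, which is exact by memorylessness.  If the total propensity is
#' zero the system idles until the next perturbation or the horizon.
#'
#' States are recorded on the grid `t = 0, 1/r, 2/r, ...` up to and
#' including the horizon (`r = samples_per_unit`), plus any
#' `extra_sample_times`; the state recorded at time `t` reflects every
#' reaction and perturbation with occurrence time `<= t`.
#'
#' Calling again with the same arguments and seed reproduces the trajectory
#' bit for bit.  The global RNG state is restored on exit.
#'
#' @param network A `crn_network`.
#' @param initial Named integer vector of initial counts (unnamed species
#'   start at 0).
#' @param horizon Simulation end time (> 0).
#' @param perturbations List of [perturbation()] objects with times in
#'   `[0, horizon]`.
#' @param samples_per_unit Sampling rate (samples per unit time).
#' @param extra_sample_times Additional off-grid sample times.
#' @param seed Integer seed for this trace.
#' @param record_events If `TRUE`, individual reaction firings are appended
#'   to the event log (use only for small systems).
#' @return A `crn_trajectory`: list with `times`, `counts` (samples x
#'   species integer matrix), `seed`, `events` (data frame
#'   `time,label,species,delta`), and `n_events` (total reactions fired).
#' @examples
#' net <- parse_network("X -> Y @ 1\nY -> X @ 1")
#' tr <- simulate_crn(net, c(X = 100), horizon = 5, seed = 1)
#' tail(tr$counts)
#' @export
simulate_crn <- function(network, initial, horizon,
                         perturbations = list(),
                         samples_per_unit = 100,
                         extra_sample_times = numeric(0),
                         seed = 1L,
                         record_events = FALSE) {
  stopifnot(inherits(network, "crn_network"), horizon > 0,
            samples_per_unit > 0)
  if (inherits(perturbations, "crn_perturbation")) {
    perturbations <- list(perturbations)
  }
  ptimes <- vapply(perturbations, `[[`, numeric(1), "time")
  if (length(ptimes)) {
    if (is.unsorted(ptimes)) {
      ord <- order(ptimes)
      perturbations <- perturbations[ord]
      ptimes <- ptimes[ord]
    }
    if (any(ptimes > horizon)) {
      stop("perturbation times must not exceed the horizon", call. = FALSE)
    }
  }

  comp <- .compile_network(network)
  x <- .full_counts(network, initial)

  grid <- seq(0, horizon, by = 1 / samples_per_unit)
  if (grid[length(grid)] < horizon - 1e-12) grid <- c(grid, horizon)
  grid <- sort(unique(c(grid, extra_sample_times)))
  grid <- grid[grid <= horizon + 1e-12]

  # pre-draw environment uniforms, one per perturbation, from a separate
  # stream; then seed the CRN stream
  old_rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
  }, add = TRUE)
  env_u <- numeric(0)
  if (length(perturbations)) {
    set.seed(.env_seed(seed))
    env_u <- runif(length(perturbations))
  }
  set.seed(seed)

  n_samp <- length(grid)
  samples <- matrix(NA_integer_, n_samp, length(comp$species),
                    dimnames = list(NULL, comp$species))
  ev_time <- numeric(0); ev_label <- character(0)
  ev_species <- character(0); ev_delta <- numeric(0)
  n_events <- 0
  sp <- 1L  # next grid slot
  t_cur <- 0

  boundaries <- c(ptimes, horizon)
  pert_at <- c(seq_along(perturbations), NA_integer_)

  # perturbations at t = 0 are applied before the t = 0 sample; otherwise
  # the initial state is recorded now
  if (!length(ptimes) || ptimes[[1]] > 1e-12) {
    while (sp <= n_samp && grid[[sp]] <= 1e-12) {
      samples[sp, ] <- x
      sp <- sp + 1L
    }
  }
  k <- 1L
  while (k <= length(boundaries)) {
    t_next <- boundaries[[k]]
    if (t_next > t_cur) {
      in_seg <- grid[grid > t_cur + 1e-12 & grid < t_next - 1e-12]
      res <- ssa_segment(comp$react_ptr, comp$react_idx, comp$react_mult,
                         comp$net_ptr, comp$net_idx, comp$net_delta,
                         comp$rates, unname(x), t_cur, t_next,
                         in_seg, record_events, -1L, 0L)
      if (length(in_seg)) {
        samples[sp + seq_along(in_seg) - 1L, ] <- res$samples
        sp <- sp + length(in_seg)
      }
      x <- setNames(res$state, comp$species)
      n_events <- n_events + res$n_events
      if (record_events && length(res$event_times)) {
        ev_time <- c(ev_time, res$event_times)
        ev_label <- c(ev_label,
                      vapply(network$reactions[res$event_rxn],
                             .format_reaction, character(1)))
        ev_species <- c(ev_species, rep(NA_character_,
                                        length(res$event_times)))
        ev_delta <- c(ev_delta, rep(NA_real_, length(res$event_times)))
      }
      t_cur <- t_next
    }
    pi_ <- pert_at[[k]]
    if (!is.na(pi_)) {
      p <- perturbations[[pi_]]
      updates <- p$action(x, t_cur, env_u[[pi_]])
      note <- attr(updates, "note")
      res <- .apply_updates(x, updates)
      x <- res$counts
      if (length(res$applied)) {
        for (ap in res$applied) {
          ev_time <- c(ev_time, t_cur)
          ev_label <- c(ev_label, if (!is.null(note)) note else p$label)
          ev_species <- c(ev_species, ap$species)
          ev_delta <- c(ev_delta, ap$delta)
        }
      } else {
        ev_time <- c(ev_time, t_cur)
        ev_label <- c(ev_label, if (!is.null(note)) note else p$label)
        ev_species <- c(ev_species, NA_character_)
        ev_delta <- c(ev_delta, 0)
      }
    }
    # samples that coincide with this boundary see the post-perturbation state
    while (sp <= n_samp && grid[[sp]] <= t_cur + 1e-12) {
      samples[sp, ] <- x
      sp <- sp + 1L
    }
    k <- k + 1L
  }

  events <- data.frame(time = ev_time, label = ev_label,
                       species = ev_species, delta = ev_delta,
                       stringsAsFactors = FALSE)
  if (nrow(events) > 1L) events <- events[order(events$time), , drop = FALSE]
  structure(list(times = grid, counts = samples, seed = as.integer(seed),
                 events = events, n_events = n_events,
                 species = comp$species),
            class = "crn_trajectory")
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat(sprintf(
    "<crn_trajectory: %d samples x %d species, t in [%g, %g], seed %d, %g reactions>\n",
    length(x$times), ncol(x$counts), min(x$times), max(x$times), x$seed,
    x$n_events))
  invisible(x)
}

#' Plot a trajectory
#'
#' @param x A `crn_trajectory`.
#' @param species Species to draw (default all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.crn_trajectory <- function(x, species = NULL, ...) {
  sp <- species %||% x$species
  graphics::matplot(x$times, x$counts[, sp, drop = FALSE], type = "l",
                    lty = 1, xlab = "time", ylab = "count", ...)
  graphics::legend("topright", legend = sp, col = seq_along(sp), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Run an ensemble of independent trajectories
#'
#' Per-trace seeds derive deterministically from `master_seed` and the trace
#' index, so the same master seed always reproduces the same ensemble and
#' trace `i` can be re-run in isolation.
#'
#' @inheritParams simulate_crn
#' @param master_seed Integer master seed.
#' @param n Number of replicates (>= 1).
#' @return A `crn_ensemble`: list with `trajectories` and `master_seed`.
#' @export
run_crn_ensemble <- function(network, initial, horizon,
                             perturbations = list(),
                             samples_per_unit = 100,
                             extra_sample_times = numeric(0),
                             master_seed = 1L, n = 1L,
                             record_events = FALSE) {
  stopifnot(n >= 1)
  trajectories <- lapply(seq_len(n), function(i) {
    simulate_crn(network, initial, horizon, perturbations,
                 samples_per_unit, extra_sample_times,
                 seed = .derive_seed(master_seed, i),
                 record_events = record_events)
  })
  structure(list(trajectories = trajectories,
                 master_seed = as.integer(master_seed)),
            class = "crn_ensemble")
}

#' @export
print.crn_ensemble <- function(x, ...) {
  cat(sprintf("<crn_ensemble: %d trajectories, master seed %d>\n",
              length(x$trajectories), x$master_seed))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Writes `time,<species...>` rows (integer counts); with `events_file`,
#' also the event log as `time,label,species,delta`.
#'
#' @param trajectory A `crn_trajectory`.
#' @param file Path for the sample CSV.
#' @param events_file Optional path for the event-log CSV.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, file, events_file = NULL) {
  df <- data.frame(time = trajectory$times, trajectory$counts,
                   check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (!is.null(events_file)) {
    write.csv(trajectory$events, events_file, row.names = FALSE)
  }
  invisible(file)
}

# Internal fast path used by the experiment procedures: run one trace and
# return only the counts at the requested sample times (matrix), skipping
# trajectory-object construction.  `comp` is a .compile_network() result.
.run_sampled <- function(comp, x0, horizon, ptimes, pactions, sample_times,
                         seed) {
  old_rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
  }, add = TRUE)
  env_u <- numeric(0)
  if (length(ptimes)) {
    set.seed(.env_seed(seed))
    env_u <- runif(length(ptimes))
  }
  set.seed(seed)
  x <- x0
  out <- matrix(NA_integer_, length(sample_times), length(x))
  t_cur <- 0
  sp <- 1L
  if (!length(ptimes) || ptimes[[1]] > 1e-12) {
    while (sp <= length(sample_times) && sample_times[[sp]] <= 1e-12) {
      out[sp, ] <- x
      sp <- sp + 1L
    }
  }
  boundaries <- c(ptimes, horizon)
  for (k in seq_along(boundaries)) {
    t_next <- boundaries[[k]]
    if (t_next > t_cur) {
      in_seg <- sample_times[sample_times > t_cur + 1e-12 &
                               sample_times < t_next - 1e-12]
      res <- ssa_segment(comp$react_ptr, comp$react_idx, comp$react_mult,
                         comp$net_ptr, comp$net_idx, comp$net_delta,
                         comp$rates, x, t_cur, t_next, in_seg, FALSE,
                         -1L, 0L)
      if (length(in_seg)) {
        out[sp + seq_along(in_seg) - 1L, ] <- res$samples
        sp <- sp + length(in_seg)
      }
      x <- res$state
      t_cur <- t_next
    }
    if (k <= length(pactions)) {
      x <- pactions[[k]](x, env_u[[k]])
    }
    while (sp <= length(sample_times) && sample_times[[sp]] <= t_cur + 1e-12) {
      out[sp, ] <- x
      sp <- sp + 1L
    }
  }
  out
}
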