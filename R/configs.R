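# Experiment configuration files: canned configurations for the reference
# experiments, YAML serialization, and conversion into system/environment
# specifications.

.canned_ids <- c("fig1e", "fig2", "fig3b", "fig3d", "fig4b", "fig4c",
                 "fig5b", "suppA", "suppB", "suppC", "suppE")

#' Canned experiment configurations
#'
#' Returns a complete configuration (initial counts, rate constants,
#' stimulus schedule, detection rule, feedback policy, horizon) for the
#' library's reference experiments.  Seeds are left to the caller.
#'
#' Available ids:
#' * `fig1e` — binary decision system, 100 decision molecules, weights
#'   60/40, several sequential stimulus cycles, no feedback.
#' * `fig2` — single-decision transfer-curve protocol (procedure config).
#' * `fig3b` — binary operant conditioning: 50/50 weights, 20 cycles,
#'   probabilistic feedback (2/3 Good for X, inverse for Y), 10 feedback
#'   molecules, threshold 90.
#' * `fig3d` — as `fig3b` but 50 cycles with the policy inverted at
#'   t = 200 (dynamic environment).
#' * `fig4b` — ternary system with response species, no feedback.
#' * `fig4c` — ternary response-based conditioning: 80 cycles of 4 on /
#'   6 off, detection on responses with threshold 40, favored response
#'   cycling R1 -> R2 (t >= 200) -> R3 (t >= 500).
#' * `fig5b` — weight forgetting: kBias = 3, 500+500 weights, weight-reset
#'   module, deterministic 200-Good feedback for X only, 10 cycles of
#'   50 on / 150 off.
#' * `suppA` — first-passage reset-time procedure (procedure config).
#' * `suppB` — sequential-decision procedure (procedure config).
#' * `suppC` — ternary choice with 99 individuals (33:33:33).
#' * `suppE` — decision-erasure variant of the binary system.
#'
#' @param figure_id One of the ids above.
#' @return A nested configuration list with blocks `system`,
#'   `environment`, `run` (or `procedure` for procedure configs).
#' @export
canned_config <- function(figure_id) {
  if (!figure_id %in% .canned_ids) {
    stop("unknown config id '", figure_id, "'; valid ids: ",
         paste(.canned_ids, collapse = ", "), call. = FALSE)
  }
  base_rates <- list(kNoise = 1, kAM = 1, kBias = 30, kFB = 1, kFBDeg = 1)
  pol_fav_X <- list(
    list(from_time = 0,
         rules = list(X = c(2 / 3, 1 / 3, 10), Y = c(1 / 3, 2 / 3, 10))))
  switch(figure_id,
    fig1e = list(
      system = list(states = c("X", "Y"),
                    counts = list(X = 50, Y = 50, WX = 60, WY = 40),
                    rates = base_rates,
                    modules = list()),
      environment = list(
        stimulus = list(cycles = 5, on = 0.5, off = 6, amount = 100),
        detection = list(threshold = 90, watch = c(X = "X", Y = "Y")),
        policy = list(list(from_time = 0, rules = list()))),
      run = list(horizon = 32.5, samples_per_unit = 100)),
    fig2 = list(
      procedure = list(type = "transfer_curve", kBias = 30,
                       n_total_weights = 100, n_traces = 10000,
                       n_grid = 25, state_total = 100, threshold = 90,
                       horizon = 0.5, stimulus_time = 0.45,
                       classify_time = 0.475, stimulus_amount = 100)),
    fig3b = list(
      system = list(states = c("X", "Y"),
                    counts = list(X = 50, Y = 50, WX = 50, WY = 50),
                    rates = base_rates,
                    modules = list(feedback = TRUE)),
      environment = list(
        stimulus = list(cycles = 20, on = 4, off = 6, amount = 100),
        detection = list(threshold = 90, watch = c(X = "X", Y = "Y")),
        policy = pol_fav_X),
      run = list(horizon = 200, samples_per_unit = 100)),
    fig3d = list(
      system = list(states = c("X", "Y"),
                    counts = list(X = 50, Y = 50, WX = 50, WY = 50),
                    rates = base_rates,
                    modules = list(feedback = TRUE)),
      environment = list(
        stimulus = list(cycles = 50, on = 4, off = 6, amount = 100),
        detection = list(threshold = 90, watch = c(X = "X", Y = "Y")),
        policy = c(pol_fav_X,
                   list(list(from_time = 200,
                             rules = list(X = c(1 / 3, 2 / 3, 10),
                                          Y = c(2 / 3, 1 / 3, 10)))))),
      run = list(horizon = 500, samples_per_unit = 100)),
    fig4b = list(
      system = list(states = c("X", "Y", "Z"),
                    responses = c("R1", "R2", "R3"),
                    counts = list(X = 33, Y = 33, Z = 33,
                                  WX = 33, WY = 33, WZ = 34),
                    rates = c(base_rates,
                              list(kResponse = 1, kResponseRepression = 1,
                                   kResponseDecay = 1)),
                    modules = list(response = TRUE)),
      environment = list(
        stimulus = list(cycles = 5, on = 4, off = 6, amount = 100),
        detection = list(threshold = 40,
                         watch = c(R1 = "R1", R2 = "R2", R3 = "R3")),
        policy = list(list(from_time = 0, rules = list()))),
      run = list(horizon = 50, samples_per_unit = 100)),
    fig4c = list(
      system = list(states = c("X", "Y", "Z"),
                    responses = c("R1", "R2", "R3"),
                    counts = list(X = 33, Y = 33, Z = 33,
                                  WX = 33, WY = 33, WZ = 34),
                    rates = c(base_rates,
                              list(kResponse = 1, kResponseRepression = 1,
                                   kResponseDecay = 1)),
                    modules = list(feedback = TRUE, response = TRUE)),
      environment = list(
        stimulus = list(cycles = 80, on = 4, off = 6, amount = 100),
        detection = list(threshold = 40,
                         watch = c(R1 = "R1", R2 = "R2", R3 = "R3")),
        policy = list(
          list(from_time = 0,
               rules = list(R1 = c(2 / 3, 1 / 3, 10),
                            R2 = c(1 / 3, 2 / 3, 10),
                            R3 = c(1 / 3, 2 / 3, 10))),
          list(from_time = 200,
               rules = list(R1 = c(1 / 3, 2 / 3, 10),
                            R2 = c(2 / 3, 1 / 3, 10),
                            R3 = c(1 / 3, 2 / 3, 10))),
          list(from_time = 500,
               rules = list(R1 = c(1 / 3, 2 / 3, 10),
                            R2 = c(1 / 3, 2 / 3, 10),
                            R3 = c(2 / 3, 1 / 3, 10))))),
      run = list(horizon = 800, samples_per_unit = 100)),
    fig5b = list(
      system = list(states = c("X", "Y"),
                    counts = list(X = 50, Y = 50, WX = 500, WY = 500),
                    rates = c(base_rates[names(base_rates) != "kBias"],
                              list(kBias = 3, kWeightReset = 0.003)),
                    modules = list(feedback = TRUE, weight_reset = TRUE)),
      environment = list(
        stimulus = list(cycles = 10, on = 50, off = 150, amount = 100),
        detection = list(threshold = 90, watch = c(X = "X", Y = "Y")),
        policy = list(list(from_time = 0,
                           rules = list(X = c(1, 0, 200))))),
      run = list(horizon = 2000, samples_per_unit = 10,
                 calibration = list(kBias = 3, n_total_weights = 1000))),
    suppA = list(
      procedure = list(type = "first_passage", n_population = 100,
                       kNoise = 1, n_traces = 10000)),
    suppB = list(
      procedure = list(type = "sequential_decisions", n_traces = 100,
                       decisions_per_trace = 100, state_total = 100,
                       kBias = 30, n_total_weights = 100,
                       on_duration = 0.05, gap = 6,
                       stimulus_amount = 100, threshold = 90)),
    suppC = list(
      system = list(states = c("X", "Y", "Z"),
                    counts = list(X = 33, Y = 33, Z = 33,
                                  WX = 33, WY = 33, WZ = 33),
                    rates = base_rates,
                    modules = list()),
      environment = list(
        stimulus = list(cycles = 5, on = 0.5, off = 6, amount = 100),
        detection = list(threshold = 90,
                         watch = c(X = "X", Y = "Y", Z = "Z")),
        policy = list(list(from_time = 0, rules = list()))),
      run = list(horizon = 32.5, samples_per_unit = 100)),
    suppE = list(
      system = list(states = c("X", "Y"),
                    counts = list(X = 50, Y = 50, WX = 60, WY = 40),
                    rates = c(base_rates, list(kErase = 1)),
                    modules = list(decision_erasure = TRUE)),
      environment = list(
        stimulus = list(cycles = 5, on = 0.5, off = 6, amount = 100),
        detection = list(threshold = 90, watch = c(X = "X", Y = "Y")),
        policy = list(list(from_time = 0, rules = list()))),
      run = list(horizon = 32.5, samples_per_unit = 100)))
}

#' Build a decision-system spec from a configuration
#'
#' @param config A configuration list with a `system` block (see
#'   [canned_config()]).
#' @return A [decision_system_spec()].
#' @export
config_to_system <- function(config) {
  sys <- config$system
  if (is.null(sys)) stop("config has no 'system' block", call. = FALSE)
  states <- unlist(sys$states)
  mods <- sys$modules %||% list()
  args <- list(
    states = states,
    weights = unlist(sys$weights) %||% paste0("W", states),
    responses = if (!is.null(sys$responses)) unlist(sys$responses),
    initial_counts = unlist(sys$counts),
    feedback = isTRUE(mods$feedback),
    response = isTRUE(mods$response),
    weight_reset = isTRUE(mods$weight_reset),
    decision_erasure = isTRUE(mods$decision_erasure))
  do.call(decision_system_spec, c(args, sys$rates))
}

#' Build an environment spec from a configuration
#'
#' @param config A configuration list with an `environment` block.
#' @return An [environment_spec()].
#' @export
config_to_environment <- function(config) {
  env <- config$environment
  if (is.null(env)) stop("config has no 'environment' block", call. = FALSE)
  st <- env$stimulus
  watch <- unlist(env$detection$watch)
  pieces <- lapply(env$policy, function(p) {
    list(from_time = p$from_time,
         rules = lapply(p$rules, function(e) as.numeric(unlist(e))))
  })
  environment_spec(
    schedule = stimulus_schedule(st$cycles, st$on, st$off, st$amount,
                                 stimulus = st$species %||% "Stimulus"),
    detection = detection_rule(watch, env$detection$threshold),
    policy = feedback_policy(pieces),
    good = env$good %||% "Good", bad = env$bad %||% "Bad")
}

#' Read / write experiment configurations as YAML
#'
#' @param file Path to a YAML file.
#' @param config A configuration list.
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `file` invisibly.
#' @export
read_config <- function(file) {
  yaml::read_yaml(file)
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

#' Run a conditioning configuration
#'
#' Convenience wrapper: builds the system and environment from a
#' configuration and runs [conditioning_run()].
#'
#' @param config A configuration list with `system`, `environment` and
#'   `run` blocks.
#' @param seed Integer seed.
#' @param curve Optional calibration [transfer_curve()].
#' @return A `conditioning_result`.
#' @export
run_config <- function(config, seed = 1, curve = NULL) {
  spec <- config_to_system(config)
  env <- config_to_environment(config)
  conditioning_run(spec, env, horizon = config$run$horizon, seed = seed,
                   curve = curve,
                   samples_per_unit = config$run$samples_per_unit %||% 100)
}
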