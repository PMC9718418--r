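# Experiment procedures: calibration, first-passage, sequential decisions,
# conditioning, ensembles and canned configurations.

test_that("calibrate_probability interpolates the transfer curve linearly", {
  curve <- data.frame(fraction = c(0, 0.4, 0.6, 1),
                      p_x = c(0, 0.3, 0.7, 1))
  # exact at grid points
  expect_equal(calibrate_probability(40, 60, curve), 0.3)
  expect_equal(calibrate_probability(60, 40, curve), 0.7)
  # linear midpoint between grid points
  expect_equal(calibrate_probability(50, 50, curve), 0.5)
  expect_equal(calibrate_probability(1, 1, curve), 0.5)
  expect_error(calibrate_probability(0, 0, curve), "positive")
})

test_that("crossing_time interpolates the first crossing after the flip", {
  times <- seq(0, 40, by = 1)
  p <- ifelse(times <= 20, 0.6, 0.6 - 0.01 * (times - 20))
  # linear descent through 0.5 at t = 30 -> duration 10
  expect_equal(crossing_time(times, p, flip_time = 20), 10)
  expect_true(is.na(crossing_time(times, rep(0.6, 41), 20)))
  expect_error(crossing_time(times, p, flip_time = 100), "flip_time")
})

test_that("first-passage reset times behave as a birth-death first-passage", {
  # degenerate start: already at the target
  fp0 <- first_passage_reset(n_population = 100, n_traces = 10,
                             master_seed = 1, start_x = 50)
  expect_true(all(fp0$times == 0))

  # doubling kNoise halves every sampled time exactly under the same seeds
  a <- first_passage_reset(n_traces = 200, master_seed = 5, kNoise = 1)
  b <- first_passage_reset(n_traces = 200, master_seed = 5, kNoise = 2)
  expect_equal(a$times, 2 * b$times)
})

test_that("sequential decisions reduce to single decisions and warn on short gaps", {
  expect_warning(
    sequential_decisions(60, 40, n_traces = 1, decisions_per_trace = 2,
                         master_seed = 1, gap = 1),
    "reset time")

  seq1 <- sequential_decisions(60, 40, n_traces = 400,
                               decisions_per_trace = 1, master_seed = 31)
  single <- decision_probability(60, 40, n_traces = 400, master_seed = 32)
  se <- sqrt(2) * binom_se(0.7, 400)
  expect_lt(abs(seq1$p_x - single$p_x), 4 * se)
  expect_equal(seq1$n_decisions, 400)
})

test_that("conditioning runs log feedback and attach calibrated probabilities", {
  curve <- data.frame(fraction = seq(0, 1, 0.25),
                      p_x = c(0, 0.2, 0.5, 0.8, 1))
  cfg <- canned_config("fig3b")
  cfg$environment$stimulus$cycles <- 5
  cfg$run$horizon <- 50
  res <- run_config(cfg, seed = 2, curve = curve)
  expect_s3_class(res, "conditioning_result")
  expect_equal(nrow(res$feedback_log), 5)
  expect_equal(res$feedback_log$cycle, 1:5)
  expect_equal(res$feedback_log$time, c(2, 12, 22, 32, 42))
  expect_length(res$p_x, length(res$trajectory$times))
  # calibrated trace agrees with direct calibration of the weight counts
  expect_equal(res$p_x,
               calibrate_probability(res$trajectory$counts[, "WX"],
                                     res$trajectory$counts[, "WY"], curve))
  # injections recorded in the log match Good/Bad additions of 10
  inj <- res$feedback_log[res$feedback_log$response != "none", ]
  expect_true(all(inj$delta == 10))
  expect_true(all(inj$species %in% c("Good", "Bad")))
})

test_that("ensemble statistics require compatible replicates", {
  curve <- data.frame(fraction = c(0, 1), p_x = c(0, 1))
  cfg <- canned_config("fig3b")
  cfg$environment$stimulus$cycles <- 2
  cfg$run$horizon <- 20
  spec <- config_to_system(cfg)
  env <- config_to_environment(cfg)
  res <- conditioning_ensemble(spec, env, 20, master_seed = 3, n = 3,
                               curve = curve, samples_per_unit = 10)
  stats <- ensemble_probability(res)
  expect_equal(names(stats), c("time", "mean_p", "sd_p"))
  expect_equal(nrow(stats), length(res[[1]]$trajectory$times))
  expect_true(all(stats$sd_p >= 0))

  # identical replicates -> zero spread
  twin <- ensemble_probability(list(res[[1]], res[[1]]))
  expect_true(all(twin$sd_p == 0))

  expect_error(ensemble_probability(res[1]), "at least 2")
  other <- conditioning_run(spec, env, 20, seed = 9, curve = curve,
                            samples_per_unit = 5)
  expect_error(ensemble_probability(list(res[[1]], other)),
               "different sample grids")
})

test_that("canned configurations carry the reference experiment settings", {
  expect_error(canned_config("fig9"), "fig3b")  # error lists the valid ids

  f3 <- canned_config("fig3b")
  expect_equal(unlist(f3$system$counts),
               c(X = 50, Y = 50, WX = 50, WY = 50))
  expect_equal(f3$environment$stimulus$cycles, 20)
  expect_equal(f3$environment$detection$threshold, 90)
  expect_equal(f3$environment$policy[[1]]$rules$X, c(2 / 3, 1 / 3, 10))

  f3d <- canned_config("fig3d")
  expect_length(f3d$environment$policy, 2)
  expect_equal(f3d$environment$policy[[2]]$from_time, 200)
  expect_equal(f3d$environment$policy[[2]]$rules$X, c(1 / 3, 2 / 3, 10))

  f4 <- canned_config("fig4c")
  expect_equal(f4$environment$stimulus[c("cycles", "on", "off", "amount")],
               list(cycles = 80, on = 4, off = 6, amount = 100))
  expect_equal(f4$environment$detection$threshold, 40)
  expect_equal(vapply(f4$environment$policy, `[[`, numeric(1), "from_time"),
               c(0, 200, 500))

  sc <- canned_config("suppC")
  expect_equal(sum(unlist(sc$system$counts[c("X", "Y", "Z")])), 99)

  f5 <- canned_config("fig5b")
  expect_equal(f5$system$rates$kBias, 3)
  expect_equal(f5$system$rates$kWeightReset, 0.003)
  expect_equal(unlist(f5$system$counts[c("WX", "WY")]),
               c(WX = 500, WY = 500))
  expect_equal(f5$environment$policy[[1]]$rules$X, c(1, 0, 200))
  expect_true(isTRUE(f5$system$modules$weight_reset))
})

test_that("configurations survive a YAML round trip", {
  cfg <- canned_config("fig3d")
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  unlink(f)
  spec_a <- config_to_system(cfg)
  spec_b <- config_to_system(back)
  expect_equal(spec_a$initial_counts[sort(names(spec_a$initial_counts))],
               spec_b$initial_counts[sort(names(spec_b$initial_counts))])
  expect_equal(spec_a$rates, spec_b$rates)
  expect_identical(format_network(build_decision_system(spec_a)),
                   format_network(build_decision_system(spec_b)))
  env_b <- config_to_environment(back)
  expect_equal(env_b$policy$from_times, c(0, 200))
  expect_equal(env_b$schedule$n_cycles, 50)
})

test_that("a small transfer curve is flat at kBias = 0 and tunable otherwise", {
  flat <- transfer_curve(kBias = 0, n_traces = 400, n_grid = 5,
                         master_seed = 17)
  expect_s3_class(flat, "transfer_curve")
  expect_equal(flat$fraction, seq(0, 1, length.out = 5))
  expect_true(all(abs(flat$p_x - 0.5) < 5 * binom_se(0.5, 400)))
  expect_true(all(flat$p_x >= 0 & flat$p_x <= 1))
  expect_true(all(flat$n_undecided + 0 <= 400))
})
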