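# Exact-simulation semantics: sampling, perturbations, reproducibility,
# and agreement with closed-form laws.

test_that("a reaction-free system stays constant on the whole sample grid", {
  net <- reaction_network(species = c("X"))
  tr <- simulate_crn(net, c(X = 7), horizon = 1, samples_per_unit = 10,
                     seed = 1)
  expect_equal(tr$times, seq(0, 1, by = 0.1))
  expect_true(all(tr$counts[, "X"] == 7))
})

test_that("pure-death decay matches the analytic mean", {
  # A -> 0 at rate 1 from A(0) = 100: E[A(1)] = 100 exp(-1), Var = 100 e^-1 (1 - e^-1)
  net <- parse_network("A -> 0 @ 1")
  ens <- run_crn_ensemble(net, c(A = 100), horizon = 1,
                          samples_per_unit = 1, master_seed = 42, n = 10000)
  finals <- vapply(ens$trajectories,
                   function(tr) tr$counts[nrow(tr$counts), "A"], numeric(1))
  mu <- 100 * exp(-1)
  se <- sqrt(mu * (1 - exp(-1)) / length(finals))
  expect_lt(abs(mean(finals) - mu), 3 * se)
})

test_that("symmetric isomerization reaches the Binomial(N, 1/2) stationary law", {
  net <- parse_network("X -> Y @ 1\nY -> X @ 1")
  tr <- simulate_crn(net, c(X = 100), horizon = 2000, samples_per_unit = 1,
                     seed = 7)
  # discard the transient; relaxation time is 1/(2 kNoise) = 0.5
  xs <- tr$counts[tr$times > 100, "X"]
  expect_lt(abs(mean(xs) - 50), 0.8)   # SE ~ 5 / sqrt(1900) ~ 0.11
  expect_lt(abs(var(xs) - 25), 5)
})

test_that("trajectories and ensembles replay bit-for-bit from their seeds", {
  cfg <- canned_config("fig3b")
  cfg$environment$stimulus$cycles <- 5
  spec <- config_to_system(cfg)
  env <- config_to_environment(cfg)
  net <- build_decision_system(spec)
  perts <- compile_environment(env, 50)
  a <- simulate_crn(net, spec$initial_counts, 50, perts, 10, seed = 99)
  b <- simulate_crn(net, spec$initial_counts, 50, perts, 10, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$events, b$events)

  cfg$environment$stimulus$cycles <- 1
  perts1 <- compile_environment(config_to_environment(cfg), 10)
  e1 <- run_crn_ensemble(net, spec$initial_counts, 10, perts1, 10,
                         master_seed = 5, n = 3)
  e2 <- run_crn_ensemble(net, spec$initial_counts, 10, perts1, 10,
                         master_seed = 5, n = 3)
  expect_identical(lapply(e1$trajectories, `[[`, "counts"),
                   lapply(e2$trajectories, `[[`, "counts"))

  # n = 1 equals a single simulate call with the derived trace seed
  single <- simulate_crn(net, spec$initial_counts, 10, perts1, 10,
                         seed = e1$trajectories[[1]]$seed)
  expect_identical(e1$trajectories[[1]]$counts, single$counts)
})

test_that("scaling all rates rescales time exactly under the same seed", {
  net <- build_decision_system(decision_system_spec(
    initial_counts = c(X = 50, Y = 50, WX = 60, WY = 40)))
  scaled <- reaction_network(lapply(net$reactions, function(r) {
    reaction(r$reactants, r$products, r$rate * 2)
  }))
  p1 <- list(perturbation(0.4, list(set_count("Stimulus", 100))))
  p2 <- list(perturbation(0.2, list(set_count("Stimulus", 100))))
  a <- simulate_crn(net, c(X = 50, Y = 50, WX = 60, WY = 40), 0.5, p1,
                    samples_per_unit = 10, seed = 31)
  b <- simulate_crn(scaled, c(X = 50, Y = 50, WX = 60, WY = 40), 0.25, p2,
                    samples_per_unit = 20, seed = 31)
  expect_identical(a$counts, b$counts)
  expect_equal(b$times * 2, a$times)
})

test_that("perturbations apply at their exact times with clamping", {
  net <- reaction_network(species = c("X", "Y"))
  perts <- list(
    perturbation(0.5, list(set_count("X", 5)), "set"),
    perturbation(1.0, list(add_count("X", -100)), "drain"),
    perturbation(1.5, list(add_count("Y", 3)), "boost"))
  tr <- simulate_crn(net, c(X = 7, Y = 0), horizon = 2,
                     samples_per_unit = 2, seed = 1, perturbations = perts)
  get <- function(t, s) unname(tr$counts[match(t, tr$times), s])
  expect_equal(get(0, "X"), 7)
  expect_equal(get(0.5, "X"), 5)   # sample at the perturbation time sees it
  expect_equal(get(1, "X"), 0)     # ADD clamps at zero
  expect_equal(get(1.5, "Y"), 3)
  expect_equal(tr$events$label, c("set", "drain", "boost"))
  expect_equal(tr$events$delta, c(-2, -5, 3))

  expect_error(
    simulate_crn(net, c(X = 1, Y = 0), 1,
                 list(perturbation(0.5, list(set_count("Q", 1)))), 1,
                 seed = 1),
    "unknown species")
})

test_that("a silent system idles until a perturbation wakes it", {
  # no X initially: zero total propensity is not an error
  net <- parse_network("X -> Y @ 1")
  tr <- simulate_crn(net, c(X = 0, Y = 0), horizon = 10,
                     perturbations = list(
                       perturbation(5, list(set_count("X", 50)))),
                     samples_per_unit = 1, seed = 3)
  expect_true(all(tr$counts[tr$times < 5, "Y"] == 0))
  expect_gt(tr$counts[nrow(tr$counts), "Y"], 0)
  expect_equal(rowSums(tr$counts[tr$times >= 5, ]), rep(50, 6))
})

test_that("trajectory CSV export writes the sample grid and event log", {
  net <- parse_network("X -> Y @ 1")
  tr <- simulate_crn(net, c(X = 10), horizon = 1, samples_per_unit = 2,
                     seed = 2,
                     perturbations = list(
                       perturbation(0.5, list(add_count("X", 5)), "topup")))
  f <- tempfile(fileext = ".csv")
  fe <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f, fe)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(names(df), c("time", "X", "Y"))
  expect_equal(nrow(df), 3)
  ev <- read.csv(fe)
  expect_equal(ev$label, "topup")
  unlink(c(f, fe))
})
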