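# Motif constructors and system composition.

test_that("entropy module builds the complete interconversion graph", {
  bin <- entropy_module(c("X", "Y"), 1)
  expect_length(bin$reactions, 2)
  expect_identical(format_network(bin), "X -> Y @ 1\nY -> X @ 1\n")

  tern <- entropy_module(c("X", "Y", "Z"), 1)
  expect_length(tern$reactions, 6)
  # every ordered pair appears exactly once
  pairs <- vapply(tern$reactions, function(r) {
    paste(names(r$reactants), names(r$products))
  }, character(1))
  expect_length(unique(pairs), 6)
  expect_error(entropy_module("X"), "at least 2")

  # zero rate: reactions exist but can never fire
  frozen <- entropy_module(c("X", "Y"), 0)
  expect_equal(propensity(frozen$reactions[[1]], c(X = 50, Y = 50)), 0)
})

test_that("approximate-majority module conserves the decision population", {
  bin <- am_module(c("X", "Y"))
  expect_length(bin$reactions, 3)
  tern <- am_module(c("X", "Y", "Z"))
  expect_length(tern$reactions, 6)
  s <- stoichiometry(tern)
  expect_true(all(colSums(s[c("X", "Y", "Z", "B"), ]) == 0))
  # stimulus is a pure catalyst
  expect_true(all(s["Stimulus", ] == 0))
  expect_error(am_module(c("X", "Y"), intermediate = "X"), "differ")
})

test_that("bias module recruits B via conserved weight catalysts", {
  bin <- bias_module(c("X", "Y"), c("WX", "WY"))
  expect_identical(format_network(bin),
                   "B + WX -> WX + X @ 30\nB + WY -> WY + Y @ 30\n")
  s <- stoichiometry(bin)
  expect_true(all(s[c("WX", "WY"), ] == 0))

  cat <- bias_module(c("X", "Y"), c("WX", "WY"), stimulus_catalyzed = TRUE)
  r <- cat$reactions[[1]]
  expect_true("Stimulus" %in% names(r$reactants))
  expect_true("Stimulus" %in% names(r$products))
})

test_that("feedback module converts weights under state catalysis and drains leftovers", {
  bin <- feedback_module(c("X", "Y"), c("WX", "WY"))
  expect_length(bin$reactions, 6)  # 4 conversions + 2 degradations
  tern <- feedback_module(c("X", "Y", "Z"), c("WX", "WY", "WZ"))
  expect_length(tern$reactions, 14)  # 6 Good + 6 Bad + 2 degradations

  # the weight total is invariant under every conversion
  s <- stoichiometry(tern)
  expect_true(all(colSums(s[c("WX", "WY", "WZ"), ]) == 0))

  # Good pulls a mismatched weight toward the current state
  good_x <- Filter(function(r) {
    all(c("Good", "X", "WY") %in% names(r$reactants))
  }, bin$reactions)
  expect_length(good_x, 1)
  expect_equal(sort(names(good_x[[1]]$products)), c("WX", "X"))

  # degradations
  degs <- Filter(function(r) length(r$products) == 0, bin$reactions)
  expect_length(degs, 2)
})

test_that("response module wires generation, cross-inhibition and decay", {
  tern <- response_module(c("X", "Y", "Z"), c("R1", "R2", "R3"))
  expect_length(tern$reactions, 12)  # 3 + 6 + 3
  s <- stoichiometry(tern)
  # decision species are pure catalysts of the response layer
  expect_true(all(s[c("X", "Y", "Z"), ] == 0))

  # at equal state counts the generation/repression pressure is symmetric
  # across responses
  counts <- c(X = 33, Y = 33, Z = 33, R1 = 10, R2 = 10, R3 = 10)
  drift <- sapply(c("R1", "R2", "R3"), function(resp) {
    sum(vapply(tern$reactions, function(r) {
      net <- 0
      if (resp %in% names(r$products)) net <- net + r$products[[resp]]
      if (resp %in% names(r$reactants)) net <- net - r$reactants[[resp]]
      net * propensity(r, counts)
    }, numeric(1)))
  })
  expect_true(all(abs(drift - drift[[1]]) < 1e-9))
})

test_that("weight reset and decision erasure modules have the stated structure", {
  wr <- weight_reset_module(c("WX", "WY"))
  expect_identical(format_network(wr),
                   "WX -> WY @ 0.003\nWY -> WX @ 0.003\n")
  expect_true(all(colSums(stoichiometry(wr)) == 0))

  er <- decision_erasure_module(c("X", "Y"))
  expect_identical(format_network(er), "X -> B @ 1\nY -> B @ 1\n")
  s <- stoichiometry(er)
  expect_true(all(colSums(s[c("X", "Y", "B"), ]) == 0))
})

test_that("without stimulus the erasure system converges to all-B", {
  spec <- decision_system_spec(
    initial_counts = c(X = 50, Y = 50, WX = 60, WY = 40),
    decision_erasure = TRUE)
  net <- build_decision_system(spec)
  tr <- simulate_crn(net, spec$initial_counts, horizon = 15,
                     samples_per_unit = 1, seed = 8)
  final <- tr$counts[nrow(tr$counts), ]
  expect_equal(unname(final[["B"]]), 100)
  expect_equal(unname(final[["X"]] + final[["Y"]]), 0)
})

test_that("composed systems have the expected reaction counts", {
  basic <- build_decision_system(decision_system_spec())
  expect_length(basic$reactions, 7)   # 2 entropy + 3 AM + 2 bias

  cond <- build_decision_system(decision_system_spec(feedback = TRUE))
  expect_length(cond$reactions, 13)   # + 4 feedback + 2 degradations

  tern <- build_decision_system(decision_system_spec(
    states = c("X", "Y", "Z"), responses = c("R1", "R2", "R3"),
    initial_counts = c(X = 33, Y = 33, Z = 33, WX = 33, WY = 33, WZ = 34),
    feedback = TRUE, response = TRUE))
  expect_length(tern$reactions, 41)   # 6 + 6 + 3 + 14 + 12

  expect_error(decision_system_spec(states = c("X", "Y"),
                                    weights = c("X", "WY")),
               "collide")
})

test_that("label-swap symmetry: mirrored weights mirror the decision", {
  a <- decision_probability(wx = 60, wy = 40, n_traces = 1500,
                            master_seed = 21)
  b <- decision_probability(wx = 40, wy = 60, n_traces = 1500,
                            master_seed = 22)
  se <- sqrt(binom_se(0.7, 1500)^2 + binom_se(0.7, 1500)^2)
  expect_lt(abs(a$p_x - b$p_y), 4 * se)
})

test_that("with kBias = 0 and equal states the choice is unbiased", {
  est <- decision_probability(wx = 60, wy = 40, kBias = 0, n_traces = 2000,
                              master_seed = 13)
  expect_lt(abs(est$p_x - 0.5), 4 * binom_se(0.5, 2000))
})
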