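test_that("the walk is reproducible, burn-in trimmed, and uniform when flat", {
  flat <- toy_landscape(rep(0, 2^4), 4)
  w1 <- metropolis_walk(flat, n_steps = 5000, seed = 3)
  w2 <- metropolis_walk(flat, n_steps = 5000, seed = 3)
  expect_identical(w1, w2)
  expect_length(w1, 5000 - 100)
  # on a flat landscape every proposal is accepted: no repeated stays
  expect_true(all(w1[-1] != w1[-length(w1)]))
  # visit frequencies uniform within Monte-Carlo error
  freq <- tabulate(metropolis_walk(flat, n_steps = 2e4, seed = 4) + 1L, 16) / (2e4 - 100)
  expect_lt(max(abs(freq - 1 / 16)), 0.02)
  expect_error(metropolis_walk(flat, n_steps = 50, seed = 1, burn_in = 100),
               "exceed")
})

test_that("walk visit frequencies converge to the Boltzmann distribution", {
  params <- moderate_params()
  ls <- build_landscape(params)
  p <- boltzmann_distribution(params)
  w <- metropolis_walk(ls, n_steps = 3e5, seed = 9)
  freq <- tabulate(w + 1L, 128) / length(w)
  tv <- 0.5 * sum(abs(freq - p))
  expect_lt(tv, 0.02)
})

test_that("the Metropolis kernel satisfies detailed balance analytically", {
  params <- planted_params("asd_like")
  ls <- build_landscape(params)
  E <- ls$energies
  p <- boltzmann_distribution(params)
  for (code in c(0, 7, 52, 65, 100, 127)) {
    for (b in 0:6) {
      nb <- bitwXor(code, 2^b)
      k_fwd <- min(1, exp(E[code + 1] - E[nb + 1])) / 7
      k_bwd <- min(1, exp(E[nb + 1] - E[code + 1])) / 7
      expect_equal(p[code + 1] * k_fwd, p[nb + 1] * k_bwd, tolerance = 1e-12)
    }
  }
})

test_that("state sequences preserve length and follow the basin map", {
  ls <- toy_landscape(c(0, 2, 3, -1))
  bm <- assign_basins(ls)
  tree <- build_disconnectivity_graph(ls)
  part <- define_brain_states(tree, bm,
                              list(major1 = 3L, major2 = 0L,
                                   minor1 = integer(0), minor2 = integer(0)))
  st <- to_state_sequence(c(0L, 1L, 2L, 3L), part)
  expect_equal(as.character(st), c("major2", "major1", "major1", "major1"))
  expect_length(to_state_sequence(rep(3L, 10), part), 10)
  expect_error(to_state_sequence(4L, part), "out of range")
})

test_that("transition classification implements the adopted definitions", {
  res <- classify_transitions(c("major1", "major1", "minor1", "major2"))
  expect_equal(res$direct, 0L)
  expect_equal(res$indirect, 1L)

  res2 <- classify_transitions(c("major1", "major2", "major1"))
  expect_equal(res2$direct, 2L)
  expect_equal(res2$indirect, 0L)

  # same-major excursion through the intermediate state is not a transition
  res3 <- classify_transitions(c("major1", "minor2", "major1"))
  expect_equal(res3$direct, 0L)
  expect_equal(res3$indirect, 0L)

  # trajectory ending inside the intermediate state completes nothing
  res4 <- classify_transitions(c("major1", "minor1", "minor2"))
  expect_equal(res4$indirect, 0L)

  # multi-step intermediate passages count once
  res5 <- classify_transitions(c("major2", "minor1", "minor1", "minor2", "major1"))
  expect_equal(res5$indirect, 1L)

  # stays are excluded from the transition matrix; direct + indirect
  # bounded by total label changes
  expect_equal(sum(res$matrix), 2)
  expect_lte(res$direct + res$indirect, sum(res$matrix))
})

test_that("dynamics summaries count appearances and run lengths", {
  st <- c("major1", "major1", "major2", "minor1", "major2")
  d <- summarize_dynamics(st)
  expect_equal(unname(d$appearance), c(40, 40, 20, 0))
  expect_equal(sum(d$appearance), 100)
  expect_equal(d$intermediate_freq, 20)
  expect_equal(sort(d$major_runs), c(1, 1, 2))
  # constant sequence: one run, 100% appearance
  d2 <- summarize_dynamics(rep("major1", 12))
  expect_equal(d2$major_runs, 12L)
  expect_equal(unname(d2$appearance["major1"]), 100)
  # run lengths sum to the total major-state occupancy
  withr::with_seed(6, lab <- sample(c("major1", "major2", "minor1", "minor2"),
                                    500, replace = TRUE))
  d3 <- summarize_dynamics(lab)
  expect_equal(sum(d3$major_runs), sum(lab %in% c("major1", "major2")))
  expect_equal(sum(d3$appearance), 100)
})

test_that("running CV is small late in long walks and shrinks with length", {
  params <- planted_params("td_like")
  ls <- build_landscape(params)
  bm <- assign_basins(ls)
  part <- define_brain_states(build_disconnectivity_graph(ls), bm,
                              planted_state_grouping())
  short <- running_cv(ls, part, n_steps = 5e3,
                      checkpoints = seq(2500, 5000, by = 500),
                      n_runs = 3, seed = 14)
  long <- running_cv(ls, part, n_steps = 5e4,
                     checkpoints = seq(25000, 50000, by = 5000),
                     n_runs = 3, seed = 14)
  expect_true(all(long$cv < short$cv))
  expect_error(running_cv(ls, part, n_steps = 1000, checkpoints = c(50, 900),
                          n_runs = 2, seed = 1), "checkpoints")
})
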