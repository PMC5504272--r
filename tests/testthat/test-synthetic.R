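test_that("planted parameters have the required structure", {
  for (g in c("td_like", "asd_like")) {
    p <- planted_params(g)
    expect_true(isSymmetric(p$J))
    expect_true(all(diag(p$J) == 0))
    expect_equal(p$network_names,
                 c("DMN", "SMN", "AUD", "FPN", "SAN", "ATN", "VIS"))
  }
  # both groups share the same six local minima
  m_td <- find_local_minima(build_landscape(planted_params("td_like")))
  m_asd <- find_local_minima(build_landscape(planted_params("asd_like")))
  expect_identical(m_td, m_asd)
  expect_setequal(m_td, unlist(planted_state_grouping()))
})

test_that("the group difference is confined to the designated couplings", {
  # the variants differ only along the stored-pattern outer products
  # (major couplings strengthened, minor coupling weakened); h is shared
  td <- planted_params("td_like")
  asd <- planted_params("asd_like")
  expect_equal(td$h, asd$h)
  u <- c(1, -1, -1, -1, -1, -1, 1)
  v <- c(1, 1, -1, 1, -1, -1, 1)
  w <- c(1, 1, 1, -1, -1, -1, -1)
  basis <- cbind(as.vector(u %o% u), as.vector(v %o% v), as.vector(w %o% w))
  diff <- as.vector(asd$J - td$J)
  off <- as.vector(upper.tri(td$J) | lower.tri(td$J))
  coef <- qr.solve(basis[off, ], diff[off])
  expect_lt(max(abs(basis[off, ] %*% coef - diff[off])), 1e-6)
  # direction of the planted contrast: major couplings up, minor down
  expect_gt(coef[1], 0)
  expect_gt(coef[2], 0)
  expect_lt(coef[3], 0)
})

test_that("minor basins are shallower in the ASD-like landscape", {
  sizes <- lapply(c("td_like", "asd_like"), function(g) {
    ls <- build_landscape(planted_params(g))
    bm <- assign_basins(ls)
    part <- define_brain_states(build_disconnectivity_graph(ls), bm,
                                planted_state_grouping())
    part$state_sizes
  })
  td <- sizes[[1]]; asd <- sizes[[2]]
  expect_gt(td[["minor1"]] + td[["minor2"]], asd[["minor1"]] + asd[["minor2"]])
  # TD minors ~11% each; ASD minors a few patterns only
  expect_equal(unname(td[["minor1"]]), 14 / 128)
  expect_equal(unname(td[["minor2"]]), 14 / 128)
  expect_lte(asd[["minor1"]] + asd[["minor2"]], 6 / 128)
  # minor minima sit higher in energy in the ASD-like landscape
  E_td <- build_landscape(planted_params("td_like"))$energies
  E_asd <- build_landscape(planted_params("asd_like"))$energies
  depth_td <- E_td[7 + 1] - min(E_td)
  depth_asd <- E_asd[7 + 1] - min(E_asd)
  expect_gt(depth_asd, depth_td)
})

test_that("exact sampling matches the Boltzmann distribution", {
  p0 <- mem_params(rep(0, 7), matrix(0, 7, 7))
  s <- sample_mem_series(p0, 4e4, seed = 5)
  expect_lt(max(abs(colMeans(s$values > 0) - 0.5)), 3 / sqrt(4e4))

  params <- planted_params("td_like")
  s2 <- sample_mem_series(params, 2e5, seed = 6)
  freq <- tabulate(statescape:::codes_of_rows(s2$values) + 1L, 128) / 2e5
  tv <- 0.5 * sum(abs(freq - boltzmann_distribution(params)))
  expect_lt(tv, 0.01)

  expect_identical(sample_mem_series(params, 100, seed = 7)$values,
                   sample_mem_series(params, 100, seed = 7)$values)
  expect_error(sample_mem_series(params, 100, seed = 7, mode = "bogus"))
  # markov mode returns the requested length and stays +/-1
  s3 <- sample_mem_series(params, 500, seed = 8, mode = "markov")
  expect_identical(dim(s3$values), c(500L, 7L))
  expect_true(all(s3$values %in% c(-1, 1)))
})

test_that("the continuous lift round-trips through binarization", {
  params <- planted_params("td_like")
  bts <- sample_mem_series(params, 1000, seed = 9)
  # noiseless lift: exact recovery
  clean <- lift_to_continuous(bts, noise_sd = 0, seed = 10)
  expect_equal(binarize_mean_threshold(clean)$values, bts$values,
               ignore_attr = TRUE)
  # default noise: error rate below 5%
  noisy <- lift_to_continuous(bts, noise_sd = 0.3, seed = 11)
  rec <- binarize_mean_threshold(noisy)$values
  expect_lt(mean(rec != bts$values), 0.05)
})

test_that("lifted signals inherit the planted module correlation structure", {
  params <- planted_params("td_like")
  bts <- sample_mem_series(params, 5000, seed = 12)
  cont <- lift_to_continuous(bts, noise_sd = 0.3, seed = 13)
  fc <- network_fc(cont)
  seg <- segregation_strength(fc, planted_module_specs()$intermediate)
  expect_gt(seg, 0)
  # a noise-only lift of unstructured patterns shows ~no segregation
  flat <- sample_mem_series(mem_params(rep(0, 7), matrix(0, 7, 7),
                                       network_names = params$network_names),
                            5000, seed = 14)
  seg0 <- segregation_strength(network_fc(lift_to_continuous(flat, 0.3, seed = 15)),
                               planted_module_specs()$intermediate)
  expect_lt(abs(seg0), 0.05)
})

test_that("cohorts are sized, scored and bit-reproducible", {
  cohort <- small_cohort(master_seed = 77)
  expect_equal(sum(cohort$manifest$group == "TD"), 4)
  expect_equal(sum(cohort$manifest$group == "ASD"), 4)
  expect_length(cohort$participants, 8)
  expect_identical(dim(cohort$participants[[1]]$binary$values), c(150L, 7L))

  cohort2 <- small_cohort(master_seed = 77)
  expect_identical(cohort$participants[[3]]$binary$values,
                   cohort2$participants[[3]]$binary$values)
  expect_identical(cohort$manifest$ados, cohort2$manifest$ados)

  cohort3 <- small_cohort(master_seed = 78)
  expect_false(identical(cohort$participants[[1]]$binary$values,
                         cohort3$participants[[1]]$binary$values))
})

test_that("planted behavioural correlations are recovered from the truth table", {
  cohort <- build_cohort(cohort_config(n_td = 26, n_asd = 24, T_len = 60,
                                       truth_steps = 4000),
                         master_seed = 5)
  truth <- cohort$ground_truth$truth
  mf <- cohort$manifest
  asd <- mf$group == "ASD"
  td <- !asd
  r_ados <- cor(mf$ados[asd], truth$indirect_freq[asd])
  expect_lt(abs(r_ados - (-0.47)), 0.15)
  r_fiq_td <- cor(mf$fiq[td], truth$indirect_freq[td])
  expect_lt(abs(r_fiq_td - 0.46), 0.15)
  r_fiq_asd <- cor(mf$fiq[asd], truth$mean_major_duration[asd])
  expect_lt(abs(r_fiq_asd - 0.55), 0.15)
  # the generator orthogonalizes the score noise, so the planted
  # correlations are in fact exact in-sample
  expect_lt(abs(r_ados - (-0.47)), 1e-8)
})

test_that("fitting a planted participant recovers their parameters better with more data", {
  cohort <- small_cohort(master_seed = 31, n_td = 2, n_asd = 2, T_len = 100)
  p <- cohort$participants[[1]]
  errs <- vapply(c(500, 5000, 50000), function(T_len) {
    s <- sample_mem_series(p$params, T_len, seed = 99)
    fit <- fit_mem(s)
    sqrt(mean((fit$params$J - p$params$J)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
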