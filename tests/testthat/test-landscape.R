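test_that("the landscape enumerates 2^K energies consistent with state_energy", {
  params <- planted_params("td_like")
  ls <- build_landscape(params)
  expect_length(ls$energies, 128)
  for (code in c(0, 1, 63, 127)) {
    expect_equal(ls$energies[code + 1],
                 state_energy(pattern_decode(code, 7), params))
  }
  # zero parameters: flat landscape, and strictness yields no minima
  flat <- build_landscape(mem_params(rep(0, 4), matrix(0, 4, 4)))
  expect_true(all(flat$energies == 0))
  expect_length(find_local_minima(flat), 0)
})

test_that("a dominant field makes the saturated pattern the only minimum", {
  p <- mem_params(rep(2, 5), matrix(0, 5, 5))
  ls <- build_landscape(p)
  expect_identical(find_local_minima(ls), 31L)
  bm <- assign_basins(ls)
  expect_equal(unname(bm$sizes), 1)
})

test_that("the K = 2 toy landscape has the hand-derived structure", {
  # energies by code: 00 -> 0, 01 -> 2, 10 -> 3, 11 -> -1
  ls <- toy_landscape(c(0, 2, 3, -1))
  expect_setequal(find_local_minima(ls), c(0L, 3L))
  bm <- assign_basins(ls)
  # 01 and 10 both descend to 11; 00 keeps itself
  expect_equal(bm$basin, c(0L, 3L, 3L, 3L))
  expect_equal(unname(bm$sizes[c("0", "3")]), c(1 / 4, 3 / 4))
  tree <- build_disconnectivity_graph(ls)
  # the two minima merge over the lower saddle (01, energy 2)
  expect_equal(tree$barriers["0", "3"], 2)
})

test_that("minima, basins and merge energies match brute-force oracles", {
  for (seed in 1:100) {
    ls <- random_landscape(7, seed)
    E <- ls$energies
    minima <- find_local_minima(ls)
    expect_identical(minima, oracle_minima(E, 7))
    bm <- assign_basins(ls, minima)
    desc <- vapply(0:127, oracle_descend, integer(1), E = E, K = 7)
    expect_identical(bm$basin, desc)
    expect_equal(sum(bm$sizes), 1)
  }
  # merge barriers against the igraph threshold-sweep oracle (a subset of
  # landscapes; the sweep oracle is slow)
  for (seed in 1:10) {
    ls <- random_landscape(7, seed)
    tree <- build_disconnectivity_graph(ls)
    m <- tree$minima
    for (pair in list(c(1, 2), c(1, length(m)), c(2, length(m) - 1))) {
      a <- m[pair[1]]; b <- m[pair[2]]
      if (a == b) next
      expect_equal(tree$barriers[as.character(a), as.character(b)],
                   oracle_barrier(a, b, ls$energies, 7))
    }
  }
})

test_that("merge energies dominate the leaf energies and shifts change nothing", {
  ls <- random_landscape(7, 202)
  tree <- build_disconnectivity_graph(ls)
  m <- as.character(tree$minima)
  for (i in seq_along(m)) for (j in seq_along(m)) {
    if (i == j) next
    expect_gte(tree$barriers[m[i], m[j]],
               max(tree$leaf_energies[m[i]], tree$leaf_energies[m[j]]))
  }
  # constant offset: same minima, basins, topology; heights shift by the offset
  ls2 <- toy_landscape(ls$energies + 57)
  expect_identical(find_local_minima(ls2), tree$minima)
  expect_identical(assign_basins(ls2)$basin, assign_basins(ls)$basin)
  tree2 <- build_disconnectivity_graph(ls2)
  expect_equal(tree2$height, tree$height + 57)
  expect_identical(tree2$merge, tree$merge)
})

test_that("steepest descent strictly decreases the energy along every path", {
  ls <- random_landscape(6, 77)
  E <- ls$energies
  nbr_of <- function(code) oracle_neighbours(code, 6)
  for (start in 0:63) {
    code <- start
    repeat {
      nb <- nbr_of(code)
      lo <- min(E[nb + 1])
      if (lo >= E[code + 1]) break
      nxt <- min(nb[E[nb + 1] == lo])
      expect_lt(E[nxt + 1], E[code + 1])
      code <- nxt
    }
    expect_true(code %in% find_local_minima(ls))
  }
})

test_that("explicit state grouping sums basin fractions and validates coverage", {
  params <- planted_params("td_like")
  ls <- build_landscape(params)
  bm <- assign_basins(ls)
  tree <- build_disconnectivity_graph(ls)
  part <- define_brain_states(tree, bm, planted_state_grouping())
  expect_equal(sum(part$state_sizes), 1)
  expect_equal(unname(part$state_sizes["major1"]),
               sum(bm$sizes[c("65", "75")]))
  expect_equal(unname(part$state_sizes["minor1"]), unname(bm$sizes["7"]))
  # omitting a minimum errors
  bad <- planted_state_grouping(); bad$minor2 <- NULL
  expect_error(define_brain_states(tree, bm, bad), "every minimum")
})

test_that("automatic grouping recovers the planted major/minor structure", {
  for (g in c("td_like", "asd_like")) {
    ls <- build_landscape(planted_params(g))
    bm <- assign_basins(ls)
    tree <- build_disconnectivity_graph(ls)
    auto <- define_brain_states(tree, bm, "auto")
    ref <- planted_state_grouping()
    # the two major states are the planted pairs (labels 1/2 may swap)
    majors <- list(sort(as.integer(names(auto$state_of_minimum)[auto$state_of_minimum == "major1"])),
                   sort(as.integer(names(auto$state_of_minimum)[auto$state_of_minimum == "major2"])))
    expect_setequal(lapply(majors, paste, collapse = ","),
                    lapply(list(sort(ref$major1), sort(ref$major2)), paste, collapse = ","))
    minors <- as.integer(names(auto$state_of_minimum)[startsWith(auto$state_of_minimum, "minor")])
    expect_setequal(minors, c(ref$minor1, ref$minor2))
  }
})

test_that("newick export encodes leaves and merge depths", {
  ls <- toy_landscape(c(0, 2, 3, -1))
  tree <- build_disconnectivity_graph(ls)
  nwk <- write_disconnectivity_newick(tree)
  expect_match(nwk, "^\\(")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("0", "3"))
  # leaf depths below the merge node equal merge energy - leaf energy
  expect_equal(sort(phy$edge.length), sort(c(2 - 0, 2 - (-1))))
})
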