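# Independent brute-force oracles used against the package implementations.
# These deliberately avoid the package's internal data structures and
# algorithms: plain loops, recursion and (for connectivity) igraph.

# wrap a plain energy vector as a landscape object
toy_landscape <- function(energies, K = round(log2(length(energies)))) {
  stopifnot(length(energies) == 2^K)
  structure(list(K = K, energies = energies,
                 network_names = paste0("N", seq_len(K))),
            class = "energy_landscape")
}

# neighbour codes by explicit bit arithmetic
oracle_neighbours <- function(code, K) {
  vapply(0:(K - 1), function(b) bitwXor(code, 2^b), integer(1))
}

# local minima by scanning every pattern's neighbours
oracle_minima <- function(E, K) {
  codes <- 0:(2^K - 1)
  codes[vapply(codes, function(c) {
    all(E[c + 1] < E[oracle_neighbours(c, K) + 1])
  }, logical(1))]
}

# recursive steepest descent from one pattern (lowest-code tie-break)
oracle_descend <- function(code, E, K) {
  repeat {
    nb <- oracle_neighbours(code, K)
    lo <- min(E[nb + 1])
    if (lo >= E[code + 1]) return(code)
    code <- min(nb[E[nb + 1] == lo])
  }
}

# minimax merge barrier between two minima: smallest threshold t (over the
# sorted energy values) such that both lie in one connected component of the
# subgraph induced by nodes with energy <= t
oracle_barrier <- function(a, b, E, K) {
  skip_if_not_installed("igraph")
  codes <- 0:(2^K - 1)
  edges <- do.call(rbind, lapply(codes, function(c) {
    nb <- oracle_neighbours(c, K)
    hi <- nb[nb > c]
    if (length(hi) == 0) NULL else cbind(c, hi)
  }))
  for (t in sort(unique(E))) {
    keep <- codes[E <= t]
    if (!(a %in% keep && b %in% keep)) next
    sub <- edges[E[edges[, 1] + 1] <= t & E[edges[, 2] + 1] <= t, , drop = FALSE]
    g <- igraph::graph_from_edgelist(matrix(as.character(sub), ncol = 2),
                                     directed = FALSE)
    g <- g + igraph::vertices(setdiff(as.character(keep),
                                      igraph::V(g)$name))
    comp <- igraph::components(g)$membership
    if (comp[as.character(a)] == comp[as.character(b)]) return(t)
  }
  stop("never connected")
}

# energy of one pattern by direct summation over all (i, j)
oracle_energy <- function(v, h, J) {
  e <- -sum(h * v)
  K <- length(v)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j) e <- e - 0.5 * J[i, j] * v[i] * v[j]
  }
  e
}

# adjusted standardized residual, written straight from the formula
oracle_chi2_residual <- function(tab, i, j) {
  n <- sum(tab)
  e <- sum(tab[i, ]) * sum(tab[, j]) / n
  (tab[i, j] - e) / sqrt(e * (1 - sum(tab[i, ]) / n) * (1 - sum(tab[, j]) / n))
}

# first-order partial correlation by the recursion formula
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# brute-force maximum-margin separator for 2-D separable points: scan
# boundary directions on a fine angular grid, pick the direction with the
# widest margin; returns unit normal (pointing toward class "pos") and bias
oracle_max_margin <- function(x, y, pos = "ASD", n_angle = 20000) {
  best <- list(margin = -Inf)
  for (th in seq(0, pi, length.out = n_angle)) {
    wn <- c(cos(th), sin(th))
    proj <- as.vector(x %*% wn)
    for (s in c(1, -1)) {
      lo <- min(s * proj[y == pos]); hi <- max(s * proj[y != pos])
      margin <- (lo - hi) / 2
      if (margin > best$margin) {
        best <- list(margin = margin, w = s * wn, b = -(lo + hi) / 2 * 1)
      }
    }
  }
  best
}

random_landscape <- function(K, seed) {
  withr::with_seed(seed, toy_landscape(rnorm(2^K), K))
}

# a tiny cohort configuration that keeps unit tests fast
small_cohort <- function(master_seed = 11, n_td = 4, n_asd = 4, T_len = 150) {
  build_cohort(cohort_config(n_td = n_td, n_asd = n_asd, T_len = T_len,
                             truth_steps = 3000),
               master_seed = master_seed)
}

# a moderately coupled planted model: mixes fast enough that finite-walk
# visit frequencies approach the Boltzmann distribution closely
moderate_params <- function(seed = 2) {
  withr::with_seed(seed, {
    Z <- matrix(runif(49, -0.3, 0.3), 7)
  })
  J <- (Z + t(Z)) / 2; diag(J) <- 0
  mem_params(rep(0, 7), J)
}

# all-pairs merge barriers via igraph: bottleneck (minimax) path costs equal
# path maxima on a minimum spanning tree with edge weight max(E_u, E_v)
oracle_barriers_mst <- function(E, K, minima) {
  skip_if_not_installed("igraph")
  codes <- 0:(2^K - 1)
  from <- integer(0); to <- integer(0)
  for (b in 0:(K - 1)) {
    nb <- bitwXor(codes, 2^b)
    sel <- nb > codes
    from <- c(from, codes[sel]); to <- c(to, nb[sel])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to),
               weight = pmax(E[from + 1], E[to + 1])),
    directed = FALSE,
    vertices = data.frame(name = as.character(codes)))
  tree <- igraph::mst(g)
  m <- length(minima)
  B <- matrix(NA_real_, m, m, dimnames = list(minima, minima))
  diag(B) <- E[minima + 1]
  for (i in seq_len(m - 1)) {
    paths <- igraph::shortest_paths(tree, from = as.character(minima[i]),
                                    to = as.character(minima[(i + 1):m]),
                                    weights = NA, output = "epath")$epath
    for (j in seq_along(paths)) {
      bar <- max(igraph::edge_attr(tree, "weight", paths[[j]]))
      B[i, i + j] <- bar
      B[i + j, i] <- bar
    }
  }
  B
}
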