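#' Build the exhaustive energy landscape of a pairwise model
#'
#' Enumerates all \code{2^K} activity patterns and their energies. Patterns
#' are the nodes of a hypercube graph in which two patterns are adjacent iff
#' they differ in exactly one network's activity (Hamming distance 1).
#'
#' @param params A [mem_params()] with K within the enumeration cap.
#' @return Object of class \code{energy_landscape}: list with \code{K},
#'   \code{energies} (length \code{2^K}, indexed by pattern code + 1) and
#'   \code{network_names}.
#' @export
build_landscape <- function(params) {
  stopifnot(inherits(params, "mem_params"))
  check_enumeration_cap(params$K)
  structure(list(K = params$K,
                 energies = all_energies(params),
                 network_names = params$network_names),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape> K = %d (%d patterns); energy range [%.3f, %.3f]; %d local minima\n",
              x$K, 2^x$K, min(x$energies), max(x$energies),
              length(find_local_minima(x))))
  invisible(x)
}

#' Find the local minima of an energy landscape
#'
#' A pattern is a local minimum when its energy is strictly smaller than the
#' energies of all K Hamming-1 neighbours. On a perfectly flat landscape the
#' strict inequality yields no minima.
#'
#' @param ls An [build_landscape()] result.
#' @return Integer vector of pattern codes (0-based), sorted increasing.
#' @export
find_local_minima <- function(ls) {
  stopifnot(inherits(ls, "energy_landscape"))
  nbr <- neighbour_index(ls$K)
  E <- ls$energies
  nbrE <- matrix(E[nbr], nrow = length(E))
  which(E < apply(nbrE, 1, min)) - 1L
}

#' Assign every pattern to the basin of a local minimum
#'
#' Steepest descent: from each pattern, repeatedly step to the
#' lowest-energy neighbour while one is lower than the current pattern; the
#' terminal pattern is a local minimum and the starting pattern belongs to
#' its basin. When two neighbours tie for lowest, the one with the lower
#' pattern code is taken (ties are measure-zero for generic real parameters
#' but the rule must be deterministic). A descent step onto an exact
#' plateau (neighbour energy equal to the current energy, none lower) is
#' reported as an error naming the tied patterns.
#'
#' @param ls An [build_landscape()] result.
#' @param minima Optional precomputed [find_local_minima()] result.
#' @return Object of class \code{basin_map}: list with \code{basin}
#'   (length \code{2^K}; \code{basin[code + 1]} is the 0-based code of the
#'   owning minimum), \code{minima} and \code{sizes} (named fractions of the
#'   \code{2^K} patterns, summing to 1).
#' @export
assign_basins <- function(ls, minima = find_local_minima(ls)) {
  stopifnot(inherits(ls, "energy_landscape"))
  if (length(minima) == 0) stop("landscape has no local minima")
  E <- ls$energies
  n <- length(E)
  nbr <- neighbour_index(ls$K)
  basin <- integer(n)
  is_min <- logical(n)
  is_min[minima + 1L] <- TRUE
  # process in ascending energy: the steepest-descent target of any
  # non-minimum has strictly lower energy, so it is already resolved
  for (i in order(E)) {
    if (is_min[i]) {
      basin[i] <- i - 1L
      next
    }
    nb <- nbr[i, ]
    lo <- min(E[nb])
    if (lo > E[i]) {
      stop("pattern ", i - 1L, " is a local minimum not present in `minima`")
    }
    if (lo == E[i]) {
      stop("steepest descent stalls at pattern ", i - 1L,
           ": exact energy tie with neighbour(s) ",
           paste(nb[E[nb] == lo] - 1L, collapse = ", "))
    }
    # deterministic tie-break: lowest pattern code among equally lowest
    target <- min(nb[E[nb] == lo])
    basin[i] <- basin[target]
  }
  sizes <- table(factor(basin, levels = minima)) / n
  structure(list(basin = basin, minima = minima,
                 sizes = stats::setNames(as.numeric(sizes), minima)),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat("<basin_map>", length(x$minima), "basins; sizes:",
      paste(sprintf("%d:%.3f", x$minima, x$sizes), collapse = " "), "\n")
  invisible(x)
}

#' Disconnectivity graph of the local minima
#'
#' Summarizes at what energy threshold pairs of local minima become
#' disconnected on the hypercube graph. Following the descending-threshold
#' procedure (remove all patterns with energy >= E_th, test pairwise
#' connectivity among minima, lower E_th through the sorted distinct energy
#' values until every minimum is isolated), the merge energy of two minima
#' is the energy at which they first disconnect -- equivalently the minimax
#' barrier: the smallest, over connecting paths, of the largest node energy
#' on the path. Implemented as a single ascending sweep with union-find,
#' which yields exactly those barriers.
#'
#' @param ls An [build_landscape()] result.
#' @param minima Optional precomputed [find_local_minima()] result.
#' @return Object of class \code{disconnectivity_tree}: list with
#'   \code{minima} (leaf codes), \code{leaf_energies}, \code{merge}
#'   (an hclust-style (m-1) x 2 merge matrix over the leaves), \code{height}
#'   (merge energies, non-decreasing) and \code{barriers} (full symmetric
#'   matrix of pairwise merge energies, labelled by minimum code).
#' @export
build_disconnectivity_graph <- function(ls, minima = find_local_minima(ls)) {
  stopifnot(inherits(ls, "energy_landscape"))
  m <- length(minima)
  if (m == 0) stop("landscape has no local minima")
  E <- ls$energies
  n <- length(E)
  nbr <- neighbour_index(ls$K)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  added <- logical(n)
  # cluster id (1..m leaves, then m+1, ... for merges) per union-find root
  clus <- integer(n)
  leaf_of <- integer(n)
  leaf_of[minima + 1L] <- seq_len(m)
  barriers <- matrix(NA_real_, m, m, dimnames = list(minima, minima))
  diag(barriers) <- E[minima + 1L]
  merge <- matrix(0L, max(m - 1L, 0L), 2L)
  height <- numeric(max(m - 1L, 0L))
  # members (leaf indices) per root, for barrier bookkeeping
  members <- vector("list", n)
  nmerge <- 0L
  next_id <- m

  for (i in order(E, seq_len(n))) {
    added[i] <- TRUE
    if (leaf_of[i] > 0) {
      clus[i] <- leaf_of[i]
      members[[i]] <- leaf_of[i]
    } else {
      clus[i] <- 0L
      members[[i]] <- integer(0)
    }
    for (j in nbr[i, ]) {
      if (!added[j]) next
      ri <- find(i)
      rj <- find(j)
      if (ri == rj) next
      mi <- members[[ri]]
      mj <- members[[rj]]
      if (length(mi) > 0 && length(mj) > 0) {
        # two minima groups meet: record the barrier and a tree merge
        for (a in mi) for (b in mj) {
          barriers[a, b] <- E[i]
          barriers[b, a] <- E[i]
        }
        nmerge <- nmerge + 1L
        merge[nmerge, ] <- c(merge_code(clus[ri], m), merge_code(clus[rj], m))
        height[nmerge] <- E[i]
        next_id <- next_id + 1L
        new_clus <- next_id
      } else {
        new_clus <- max(clus[ri], clus[rj])
      }
      parent[ri] <- rj
      members[[rj]] <- c(mi, mj)
      clus[rj] <- new_clus
    }
  }
  structure(list(minima = minima,
                 leaf_energies = stats::setNames(E[minima + 1L], minima),
                 merge = merge, height = height,
                 barriers = barriers),
            class = "disconnectivity_tree")
}

# default automatic cut level: the midpoint of the widest gap in the
# sorted merge energies, restricted to cuts leaving 2-4 clusters (cutting
# below merge i of m-1 leaves m - i clusters)
widest_gap_cut <- function(heights, n_leaves) {
  if (length(heights) == 0) stop("single-minimum tree cannot be cut")
  h <- sort(heights)
  m <- length(h)
  # candidate cut between h[i] and h[i+1] leaves n_leaves - i clusters;
  # cutting above all merges leaves 1 cluster (excluded)
  best <- NULL
  for (i in seq_len(m)) {
    n_cl <- n_leaves - i
    if (n_cl < 2 || n_cl > 4) next
    upper <- if (i < m) h[i + 1] else h[m] + abs(h[m]) + 1
    gap <- upper - h[i]
    if (is.null(best) || gap > best$gap) best <- list(gap = gap, cut = h[i] + gap / 2)
  }
  if (is.null(best)) {
    # fewer than 2 reachable clusters only when n_leaves <= 2: cut below all
    return(min(h) - 1)
  }
  best$cut
}

# hclust merge coding: negative leaf index, positive prior-merge index
merge_code <- function(clus_id, m) {
  if (clus_id <= m) -as.integer(clus_id) else as.integer(clus_id - m)
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat("<disconnectivity_tree>", length(x$minima), "minima:",
      paste(x$minima, collapse = ", "), "\n")
  if (length(x$height) > 0) {
    cat("  merge energies:", paste(sprintf("%.3f", x$height), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.hclust.disconnectivity_tree <- function(x, ...) {
  if (length(x$minima) < 2) stop("need at least 2 minima for an hclust tree")
  structure(list(merge = x$merge, height = x$height,
                 order = hclust_order(x$merge),
                 labels = as.character(x$minima),
                 method = "minimax barrier"),
            class = "hclust")
}

hclust_order <- function(merge) {
  walk <- function(i) {
    if (i < 0) return(-i)
    c(walk(merge[i, 1]), walk(merge[i, 2]))
  }
  walk(nrow(merge))
}

#' Export a disconnectivity tree as Newick
#'
#' Leaves are the minimum codes; branch lengths place every leaf at its own
#' energy and every internal node at its merge energy, so merge energies can
#' be read off as node depths.
#'
#' @param tree A [build_disconnectivity_graph()] result with >= 2 minima.
#' @param path Optional file; when NULL the Newick string is returned.
#' @export
write_disconnectivity_newick <- function(tree, path = NULL) {
  m <- length(tree$minima)
  if (m < 2) stop("need at least 2 minima")
  build <- function(i) {
    if (i < 0) {
      leaf <- -i
      list(label = as.character(tree$minima[leaf]),
           energy = unname(tree$leaf_energies[leaf]))
    } else {
      l <- build(tree$merge[i, 1])
      r <- build(tree$merge[i, 2])
      h <- tree$height[i]
      list(label = sprintf("(%s:%.6g,%s:%.6g)%.6g",
                           l$label, h - l$energy, r$label, h - r$energy, h),
           energy = h)
    }
  }
  nwk <- paste0(build(nrow(tree$merge))$label, ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    invisible(path)
  } else {
    nwk
  }
}

#' Group local minima into labelled brain states
#'
#' Maps each local minimum to one of the four canonical states --
#' \code{major1}, \code{major2}, \code{minor1}, \code{minor2} -- and derives
#' the pattern-level state map through the basin assignment. State sizes are
#' the summed basin fractions of the member minima. The two minor states are
#' jointly the intermediate state.
#'
#' Grouping is either explicit (a named list of minimum codes, the default
#' analysis mode when the landscape has been inspected) or automatic: the
#' disconnectivity tree is cut at a barrier level, minima whose merge
#' energies lie below the cut share a state, and the resulting clusters are
#' labelled major/minor by total basin size, \code{major1} largest. By
#' default the cut is placed in the widest gap of the sorted merge energies
#' among the cuts that yield between 2 and 4 clusters (a landscape whose
#' shallow minima have vanished then simply gets empty minor states); an
#' explicit \code{auto_cut} energy overrides the gap rule.
#'
#' @param tree A [build_disconnectivity_graph()] result.
#' @param basin_map An [assign_basins()] result for the same landscape.
#' @param grouping Either \code{"auto"} or a named list
#'   \code{list(major1 = codes, major2 = codes, minor1 = codes, minor2 =
#'   codes)} covering every minimum exactly once.
#' @param auto_cut Optional energy level at which to cut the tree when
#'   \code{grouping = "auto"}.
#' @return Object of class \code{brain_state_partition}: list with
#'   \code{state_of_minimum} (named character), \code{pattern_state}
#'   (length \code{2^K} factor-like character vector), \code{state_sizes}
#'   and \code{labels}.
#' @export
define_brain_states <- function(tree, basin_map, grouping = "auto",
                                auto_cut = NULL) {
  stopifnot(inherits(tree, "disconnectivity_tree"), inherits(basin_map, "basin_map"))
  minima <- tree$minima
  labels <- c("major1", "major2", "minor1", "minor2")
  if (identical(grouping, "auto")) {
    if (length(minima) < 2) stop("automatic grouping requires at least 2 minima")
    if (is.null(auto_cut)) auto_cut <- widest_gap_cut(tree$height, length(minima))
    cl <- stats::cutree(stats::as.hclust(tree), h = auto_cut)
    n_cl <- max(cl)
    if (n_cl > 4) {
      stop("cutting at ", format(auto_cut), " yields ", n_cl,
           " states; raise auto_cut or pass an explicit grouping")
    }
    sizes <- tapply(basin_map$sizes[as.character(minima)], cl[as.character(minima)], sum)
    ord <- order(sizes, decreasing = TRUE)
    relabel <- stats::setNames(labels[seq_len(n_cl)], names(sizes)[ord])
    state_of_minimum <- stats::setNames(unname(relabel[as.character(cl)]), names(cl))
  } else {
    stopifnot(is.list(grouping), all(names(grouping) %in% labels))
    flat <- unlist(grouping, use.names = FALSE)
    if (!setequal(flat, minima) || anyDuplicated(flat)) {
      stop("grouping must cover every minimum exactly once; missing: ",
           paste(setdiff(minima, flat), collapse = ", "))
    }
    state_of_minimum <- stats::setNames(rep(names(grouping), lengths(grouping)), flat)[as.character(minima)]
    names(state_of_minimum) <- as.character(minima)
  }
  pattern_state <- unname(state_of_minimum[as.character(basin_map$basin)])
  state_sizes <- vapply(labels, function(l) {
    sum(basin_map$sizes[names(state_of_minimum)[state_of_minimum == l]])
  }, numeric(1))
  structure(list(state_of_minimum = state_of_minimum,
                 pattern_state = pattern_state,
                 state_sizes = state_sizes,
                 labels = labels),
            class = "brain_state_partition")
}

#' @export
print.brain_state_partition <- function(x, ...) {
  cat("<brain_state_partition>",
      paste(sprintf("%s:{%s} %.1f%%", x$labels,
                    vapply(x$labels, function(l) paste(names(x$state_of_minimum)[x$state_of_minimum == l], collapse = ","), ""),
                    100 * x$state_sizes), collapse = "  "), "\n")
  invisible(x)
}

#' Tabulate a full landscape for export
#'
#' One row per pattern: code, bit string, energy, local-minimum flag, owning
#' basin and state label.
#'
#' @param ls An [build_landscape()] result.
#' @param basin_map An [assign_basins()] result.
#' @param partition Optional [define_brain_states()] result.
#' @return data.frame with \code{2^K} rows.
#' @export
landscape_table <- function(ls, basin_map, partition = NULL) {
  codes <- 0:(2^ls$K - 1)
  S <- all_patterns(ls$K)
  out <- data.frame(
    code = codes,
    pattern = apply(S, 1, function(r) paste(ifelse(r > 0, "1", "0"), collapse = "")),
    energy = ls$energies,
    is_minimum = codes %in% basin_map$minima,
    basin = basin_map$basin
  )
  if (!is.null(partition)) out$state <- partition$pattern_state
  out
}
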