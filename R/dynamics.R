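#' Metropolis random walk on the energy landscape
#'
#' Simulates brain dynamics as a Markov chain over the \code{2^K} activity
#' patterns. From the current pattern one of the K Hamming-1 neighbours is
#' proposed uniformly and accepted with probability
#' \eqn{\min(1, e^{E_{current} - E_{proposed}})}; a rejected proposal repeats
#' the current pattern (the step count always advances, which is required
#' for the chain's stationary distribution to be the Boltzmann
#' distribution). The walk starts at a uniformly random pattern and the
#' first \code{burn_in} steps are discarded.
#'
#' @param ls An [build_landscape()] result.
#' @param n_steps Total steps before burn-in removal (default 1e5).
#' @param seed Mandatory integer seed; the caller's RNG state is left
#'   untouched.
#' @param burn_in Steps discarded at the start (default 100).
#' @param init Optional starting pattern code; default uniform random.
#' @return Integer vector of length \code{n_steps - burn_in} of pattern
#'   codes (0-based), with attributes \code{seed} and \code{burn_in}.
#' @export
metropolis_walk <- function(ls, n_steps = 1e5, seed, burn_in = 100, init = NULL) {
  stopifnot(inherits(ls, "energy_landscape"))
  if (missing(seed)) stop("an explicit seed is required")
  if (n_steps <= burn_in) stop("n_steps must exceed burn_in")
  K <- ls$K
  E <- ls$energies
  nbr <- neighbour_index(K)
  # acceptance probabilities precomputed per (pattern, flipped bit)
  acc <- matrix(pmin(1, exp(E - E[nbr])), nrow = length(E))
  withr::with_seed(seed, {
    cur <- if (is.null(init)) sample.int(length(E), 1) else as.integer(init) + 1L
    bits <- sample.int(K, n_steps, replace = TRUE)
    us <- stats::runif(n_steps)
    out <- integer(n_steps)
    for (t in seq_len(n_steps)) {
      if (us[t] < acc[cur, bits[t]]) cur <- nbr[cur, bits[t]]
      out[t] <- cur
    }
  })
  structure(out[(burn_in + 1):n_steps] - 1L, seed = seed, burn_in = burn_in)
}

#' Map a pattern sequence to a brain-state sequence
#'
#' Each pattern is replaced by the state label of the basin it belongs to.
#' The same mapping serves simulated walks and empirical binarized volumes
#' (direct counting).
#'
#' @param codes Integer vector of pattern codes (0-based), e.g. a
#'   [metropolis_walk()] result or \code{pattern_code()} applied to data rows.
#' @param partition A [define_brain_states()] result.
#' @param source Tag recorded on the result: "simulated" or "empirical".
#' @return Object of class \code{state_trajectory}: character vector of
#'   state labels with attributes \code{source} and (when present)
#'   \code{seed}.
#' @export
to_state_sequence <- function(codes, partition, source = "simulated") {
  stopifnot(inherits(partition, "brain_state_partition"))
  n_pat <- length(partition$pattern_state)
  if (any(codes < 0 | codes >= n_pat)) stop("pattern code out of range")
  structure(partition$pattern_state[codes + 1L],
            source = source, seed = attr(codes, "seed"),
            class = "state_trajectory")
}

coarse_labels <- function(labels) {
  ifelse(labels %in% c("minor1", "minor2"), "intermediate", labels)
}

#' Count direct and indirect transitions between the major states
#'
#' Transitions are label changes between consecutive steps (stays
#' excluded). A \emph{direct} transition is a change from one major state
#' to the other in a single step. An \emph{indirect} transition is a
#' completed passage major_a -> (one or more consecutive intermediate
#' steps) -> major_b with b != a; excursions into the intermediate state
#' that return to the same major state, and trajectories ending inside the
#' intermediate state, contribute no transition (the strictest reading of a
#' passage "via" the intermediate state).
#'
#' @param st A [to_state_sequence()] result (or plain label vector).
#' @return List with \code{matrix} (4 x 4 transition counts between the
#'   four states, stays excluded), \code{direct}, \code{indirect},
#'   \code{n_steps}, and per-step / per-change frequencies for both
#'   transition types (both normalizations are reported).
#' @export
classify_transitions <- function(st) {
  labels <- as.character(st)
  states <- c("major1", "major2", "minor1", "minor2")
  tmat <- matrix(0L, 4, 4, dimnames = list(from = states, to = states))
  n <- length(labels)
  if (n >= 2) {
    from <- labels[-n]
    to <- labels[-1]
    chg <- from != to
    if (any(chg)) {
      tt <- table(factor(from[chg], states), factor(to[chg], states))
      tmat <- tmat + unclass(tt)
    }
  }
  direct <- tmat["major1", "major2"] + tmat["major2", "major1"]
  # indirect: compress runs, look for major / intermediate+ / other major
  runs <- rle(coarse_labels(labels))$values
  indirect <- 0L
  if (length(runs) >= 3) {
    for (i in 3:length(runs)) {
      if (runs[i] != "intermediate" && runs[i - 1] == "intermediate" &&
          runs[i - 2] != "intermediate" && runs[i] != runs[i - 2]) {
        indirect <- indirect + 1L
      }
    }
  }
  n_changes <- sum(tmat)
  list(matrix = tmat, direct = as.integer(direct), indirect = indirect,
       n_steps = n,
       direct_freq = direct / n, indirect_freq = indirect / n,
       direct_per_change = if (n_changes > 0) direct / n_changes else 0,
       indirect_per_change = if (n_changes > 0) indirect / n_changes else 0)
}

#' Summary indices of a brain-state trajectory
#'
#' Appearance frequency of each state (% of retained steps, summing to
#' 100), the intermediate-state frequency (minor1 + minor2), the direct and
#' indirect transition counts/frequencies, and the durations of the major
#' states (lengths of maximal constant runs in either major state, in
#' steps/volumes).
#'
#' @param st A [to_state_sequence()] result (or plain label vector).
#' @return Object of class \code{dynamics_indices} (a list).
#' @export
summarize_dynamics <- function(st) {
  labels <- as.character(st)
  if (length(labels) < 1) stop("empty trajectory")
  states <- c("major1", "major2", "minor1", "minor2")
  appearance <- 100 * as.numeric(table(factor(labels, states))) / length(labels)
  names(appearance) <- states
  r <- rle(labels)
  major_runs <- r$lengths[r$values %in% c("major1", "major2")]
  tr <- classify_transitions(labels)
  structure(list(
    appearance = appearance,
    intermediate_freq = appearance[["minor1"]] + appearance[["minor2"]],
    major_freq = appearance[["major1"]] + appearance[["major2"]],
    major_runs = as.integer(major_runs),
    mean_major_duration = if (length(major_runs)) mean(major_runs) else NA_real_,
    transitions = tr,
    direct_freq = 100 * tr$direct_freq,
    indirect_freq = 100 * tr$indirect_freq,
    n_steps = length(labels)
  ), class = "dynamics_indices")
}

#' @export
print.dynamics_indices <- function(x, ...) {
  cat(sprintf("<dynamics_indices> %d steps | appearance M1 %.1f%% M2 %.1f%% interm %.1f%% | direct %.3f%%/step indirect %.3f%%/step | mean major duration %.1f\n",
              x$n_steps, x$appearance[["major1"]], x$appearance[["major2"]],
              x$intermediate_freq, x$direct_freq, x$indirect_freq,
              x$mean_major_duration))
  invisible(x)
}

#' Convergence of simulated dynamics indices
#'
#' Runs \code{n_runs} independent walks and, for each, evaluates the
#' cumulative indirect-transition frequency and mean major-state duration
#' at the given checkpoints. The coefficient of variation (sd/mean) of the
#' checkpoint estimates within each run quantifies how settled the index
#' is; the run-averaged CV is returned per index. (The operationalization
#' -- cumulative estimates at checkpoints within a run -- is this package's
#' own; it is meant as a practical stability diagnostic.)
#'
#' @param ls An [build_landscape()] result.
#' @param partition A [define_brain_states()] result.
#' @param n_steps Walk length.
#' @param checkpoints Increasing step counts (after burn-in) at which the
#'   cumulative indices are evaluated.
#' @param n_runs Number of independent walks.
#' @param seed Master seed; run r uses seed + r.
#' @param burn_in Passed to [metropolis_walk()].
#' @return List with \code{cv} (named vector; NA-flagged when an index mean
#'   is 0) and \code{estimates} (checkpoints x 2 x n_runs array).
#' @export
running_cv <- function(ls, partition, n_steps = 1e5,
                       checkpoints = seq(0.5, 1, by = 0.1) * n_steps,
                       n_runs = 5, seed, burn_in = 100) {
  if (missing(seed)) stop("an explicit seed is required")
  checkpoints <- sort(unique(round(checkpoints)))
  if (any(checkpoints <= burn_in) || any(checkpoints > n_steps)) {
    stop("checkpoints must lie in (burn_in, n_steps]")
  }
  est <- array(NA_real_, dim = c(length(checkpoints), 2, n_runs),
               dimnames = list(checkpoints, c("indirect_freq", "mean_major_duration"), NULL))
  for (r in seq_len(n_runs)) {
    codes <- metropolis_walk(ls, n_steps = n_steps, seed = seed + r, burn_in = burn_in)
    labels <- to_state_sequence(codes, partition)
    for (ci in seq_along(checkpoints)) {
      d <- summarize_dynamics(labels[seq_len(checkpoints[ci] - burn_in)])
      est[ci, 1, r] <- d$indirect_freq
      est[ci, 2, r] <- d$mean_major_duration
    }
  }
  cv_one <- function(v) {
    if (anyNA(v) || mean(v) == 0) NA_real_ else stats::sd(v) / mean(v)
  }
  cv <- c(indirect_freq = mean(apply(est[, 1, , drop = FALSE], 3, cv_one)),
          mean_major_duration = mean(apply(est[, 2, , drop = FALSE], 3, cv_one)))
  list(cv = cv, estimates = est)
}
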