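# Planted cohort generator: ground-truth Ising parameters with the
# major/major/minor/minor landscape structure, exact Boltzmann samples,
# continuous surrogate signals and behavioural scores with planted effects.

# Canonical 7-network roster; column order fixes the pattern-code bit order.
PLANTED_NETWORKS <- c("DMN", "SMN", "AUD", "FPN", "SAN", "ATN", "VIS")

# Frozen planted parameters. The construction stores three +/-1 patterns
# Hopfield-style -- two overlapping "major" patterns (DMN+VIS active, and
# DMN+SMN+FPN+VIS active; Hamming distance 2, so they form a deep
# two-minimum branch) and one "minor" pattern (DMN+SMN+AUD active,
# anticorrelated with the FPN/SAN/ATN/VIS module) -- plus a frozen random
# symmetric perturbation that breaks the ties of the pure outer-product
# landscape, scaled by a common inverse-temperature factor. The accepted
# parameter set was found by bounded search over the block magnitudes and
# ships frozen below; tests assert the resulting landscape structure.
#
# td_like:  6 local minima; minor basins 14/128 each (~10.9%).
# asd_like: same 6 minima; minor basins 4/128 and 2/128 (shallower,
#           higher-energy minor wells), major couplings slightly stronger so
#           the direct major1<->major2 crossing rate stays matched.
PLANTED_H <- c(0.021935, -0.009035, 0.00581, 0.010126, 0.006468, -0.001698,
               0.024184)
PLANTED_J_UPPER_TD <- c(0.059616, -0.167477, 0.249214, 0.001296, 0.146147,
                        -0.08924, -0.683944, -0.066932, 0.288463, 0.2036,
                        -0.55229, -0.223927, 0.058637, 0.227458, 0.457763,
                        0.151448, -0.0893, -0.684626, 0.230933, -0.219504,
                        -0.191018)
PLANTED_J_UPPER_ASD <- c(0.031044, -0.310334, 0.220643, 0.029868, 0.289005,
                         -0.060668, -0.769658, -0.03836, 0.43132, 0.175028,
                         -0.638005, -0.195356, 0.201494, 0.198887, 0.543477,
                         0.294306, -0.060728, -0.77034, 0.202362, -0.362362,
                         -0.333875)

planted_J <- function(upper) {
  J <- matrix(0, 7, 7)
  J[upper.tri(J)] <- upper
  J + t(J)
}

#' Planted model parameters for a synthetic group
#'
#' Ground-truth pairwise maximum-entropy parameters whose energy landscape
#' has six local minima groupable into two major states (two minima each)
#' and two minor states (one minimum each). The TD-like variant has minor
#' basins of ~11% of the pattern space each; the ASD-like variant has the
#' same six minima but raised (shallower) minor wells with basins of
#' 1.6-3%, and slightly deepened major wells so that the direct transition
#' rate between the major states matches the TD-like variant. See the
#' methods vignette for the construction.
#'
#' @param group_kind "td_like" or "asd_like".
#' @return A [mem_params()] for K = 7 networks (DMN, SMN, AUD, FPN, SAN,
#'   ATN, VIS).
#' @export
planted_params <- function(group_kind = c("td_like", "asd_like")) {
  group_kind <- match.arg(group_kind)
  upper <- switch(group_kind,
                  td_like = PLANTED_J_UPPER_TD,
                  asd_like = PLANTED_J_UPPER_ASD)
  mem_params(PLANTED_H, planted_J(upper), network_names = PLANTED_NETWORKS)
}

#' Canonical state grouping of the planted landscape
#'
#' Maps the six planted local minima to brain-state labels. Codes 65
#' (DMN+VIS) and 75 (DMN+SMN+FPN+VIS) form major state 1; their global
#' flips 62 and 52 form major state 2; code 7 (DMN+SMN+AUD) and its flip
#' 120 are the two minor states.
#'
#' @return Named list usable as the \code{grouping} argument of
#'   [define_brain_states()].
#' @export
planted_state_grouping <- function() {
  list(major1 = c(65L, 75L), major2 = c(62L, 52L),
       minor1 = 7L, minor2 = 120L)
}

#' Module specifications of the planted parcellation
#'
#' The intermediate-state modules split the networks into the anticorrelated
#' blocks of the planted minor pattern (DMN/SMN/AUD vs FPN/SAN/ATN/VIS); the
#' major-state modules split them by the planted major pattern (DMN/VIS vs
#' the rest).
#'
#' @return List with [module_spec()]s \code{intermediate} and \code{major}.
#' @export
planted_module_specs <- function() {
  list(
    intermediate = module_spec(c("DMN", "SMN", "AUD"),
                               c("FPN", "SAN", "ATN", "VIS"),
                               name = "intermediate-state modules"),
    major = module_spec(c("DMN", "VIS"),
                        c("SMN", "AUD", "FPN", "SAN", "ATN"),
                        name = "major-state modules")
  )
}

#' Draw a binary time series from a pairwise model
#'
#' \code{iid} mode draws T patterns exactly from the enumerated Boltzmann
#' distribution (a categorical draw over the 2^K patterns -- exact, no
#' burn-in concerns). \code{markov} mode records T retained steps of the
#' Metropolis chain, which adds the temporal autocorrelation of a random
#' walk (closer to fMRI dynamics).
#'
#' @param params A [mem_params()].
#' @param T_len Number of time points.
#' @param seed Mandatory seed.
#' @param mode "iid" (default) or "markov".
#' @param participant_id Passed through to the result.
#' @return A [binary_ts()].
#' @export
sample_mem_series <- function(params, T_len, seed, mode = c("iid", "markov"),
                              participant_id = NA_character_) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required")
  S <- all_patterns(params$K)
  if (mode == "iid") {
    p <- boltzmann_distribution(params)
    codes <- withr::with_seed(seed,
      sample.int(length(p), T_len, replace = TRUE, prob = p) - 1L)
  } else {
    ls <- build_landscape(params)
    codes <- metropolis_walk(ls, n_steps = T_len + 100, seed = seed, burn_in = 100)
  }
  binary_ts(S[codes + 1L, , drop = FALSE],
            network_names = params$network_names,
            participant_id = participant_id)
}

#' Lift a binary series to continuous surrogate signals
#'
#' value = sigma_i^t + Gaussian noise. For noise_sd < 0.5 the mean-threshold
#' binarization recovers the input binary series with a low error rate
#' (< 5%), so the continuous surrogate exercises the preprocessing path
#' without changing the planted pattern statistics much.
#'
#' @param bts A [binary_ts()].
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Mandatory seed.
#' @return A [network_ts()].
#' @export
lift_to_continuous <- function(bts, noise_sd = 0.3, seed) {
  stopifnot(inherits(bts, "binary_ts"), noise_sd >= 0)
  if (missing(seed)) stop("an explicit seed is required")
  vals <- bts$values
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals), ncol(vals)))
  network_ts(vals + noise, network_names = bts$network_names,
             participant_id = bts$participant_id)
}

#' Configuration of a synthetic planted cohort
#'
#' Defaults mirror the reference study's conditions: 26 TD-like and 24
#' ASD-like participants, ~240 retained volumes each (an ~8 min scan at a
#' 2 s repetition time), K = 7 networks. Behavioural effects are planted as
#' correlations between the scores and each participant's ground-truth
#' dynamics indices: ADOS-like severity correlates negatively with the
#' indirect-transition frequency (-0.47 in the ASD-like group), FIQ-like
#' ability correlates with the indirect-transition frequency in the TD-like
#' group (+0.46) and with the major-state duration in the ASD-like group
#' (+0.55). Score means/sds follow the study's demographic table.
#'
#' @param n_td,n_asd Group sizes.
#' @param T_len Time points per participant.
#' @param noise_sd Noise sd of the continuous lift.
#' @param jitter_h,jitter_J Per-participant Gaussian jitter sds on h and J
#'   (individual variability around the group parameters).
#' @param series_mode "iid" or "markov" sampling per participant.
#' @param truth_steps Walk length used to measure each participant's
#'   ground-truth dynamics indices.
#' @param ados_r_td,ados_r_asd,fiq_r_td,fiq_r_asd Planted correlations.
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(n_td = 26, n_asd = 24, T_len = 240,
                          noise_sd = 0.3, jitter_h = 0.05, jitter_J = 0.03,
                          series_mode = c("iid", "markov"),
                          truth_steps = 2e4,
                          ados_r_td = -0.45, ados_r_asd = -0.47,
                          fiq_r_td = 0.46, fiq_r_asd = 0.55) {
  stopifnot(n_td >= 2, n_asd >= 2, T_len >= 2)
  structure(list(n_td = n_td, n_asd = n_asd, T_len = T_len,
                 noise_sd = noise_sd, jitter_h = jitter_h, jitter_J = jitter_J,
                 series_mode = match.arg(series_mode),
                 truth_steps = truth_steps,
                 ados_r_td = ados_r_td, ados_r_asd = ados_r_asd,
                 fiq_r_td = fiq_r_td, fiq_r_asd = fiq_r_asd,
                 # score location/scale: TD ADOS 1.2 +/- 1.4, ASD 12.8 +/- 3.6;
                 # FIQ 112.6 +/- 12.0 (TD), 109.9 +/- 14.2 (ASD)
                 ados_mean = c(td = 1.2, asd = 12.8),
                 ados_sd = c(td = 1.4, asd = 3.6),
                 fiq_mean = c(td = 112.6, asd = 109.9),
                 fiq_sd = c(td = 12.0, asd = 14.2)),
            class = "cohort_config")
}

# score = mean + sd * (rho * z_index + sqrt(1 - rho^2) * noise); z_index is
# the standardized ground-truth index within the group. The noise is
# orthogonalized against z_index and re-standardized, so the planted
# correlation holds exactly in the generated sample, not just in
# expectation (degenerate tiny groups fall back to raw noise).
planted_score <- function(index, rho, mean, sd, noise) {
  z <- as.numeric(scale(index))
  n <- length(z)
  e <- noise
  if (n >= 3 && stats::sd(noise) > 0) {
    e <- as.numeric(scale(stats::residuals(stats::lm(noise ~ z))))
  }
  mean + sd * (rho * z + sqrt(1 - rho^2) * e)
}

#' Generate a synthetic two-group cohort with planted ground truth
#'
#' For each participant: group parameters jittered by participant-specific
#' Gaussian noise (J kept symmetric, zero diagonal), an exact binary sample
#' of the participant's model, a continuous surrogate lift, ground-truth
#' dynamics indices measured by a Metropolis walk on the participant's own
#' landscape (labelled through the canonical planted state map), and
#' behavioural scores generated from those ground-truth indices with the
#' configured correlations. Every stochastic output derives from
#' (master_seed, participant index), so cohorts are bit-reproducible.
#'
#' @param config A [cohort_config()].
#' @param master_seed Integer master seed.
#' @return Object of class \code{cohort_dataset}: list with
#'   \code{participants} (each: id, group, seed, params, binary,
#'   continuous, truth), \code{manifest} (data.frame with group and
#'   scores), \code{config}, \code{master_seed} and \code{ground_truth}
#'   (group params, grouping, per-participant truth table).
#' @export
build_cohort <- function(config = cohort_config(), master_seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(master_seed)) stop("an explicit master seed is required")
  n <- config$n_td + config$n_asd
  groups <- c(rep("TD", config$n_td), rep("ASD", config$n_asd))
  seeds <- withr::with_seed(master_seed,
    sample.int(.Machine$integer.max - 10L, n + 2L))
  part_seeds <- seeds[seq_len(n)]

  base <- list(TD = planted_params("td_like"), ASD = planted_params("asd_like"))
  # canonical pattern -> state map, shared by both groups (the two base
  # landscapes have identical minima and state structure)
  canon <- lapply(base, function(p) {
    ls <- build_landscape(p)
    bm <- assign_basins(ls)
    define_brain_states(build_disconnectivity_graph(ls), bm,
                        grouping = planted_state_grouping())
  })

  participants <- vector("list", n)
  truth <- data.frame(participant_id = character(n), group = groups,
                      intermediate_freq = numeric(n), indirect_freq = numeric(n),
                      mean_major_duration = numeric(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- sprintf("%s_%02d", tolower(groups[i]), i)
    ps <- part_seeds[i]
    g <- groups[i]
    jit <- withr::with_seed(ps, {
      dh <- stats::rnorm(7, 0, config$jitter_h)
      Z <- matrix(stats::rnorm(49, 0, config$jitter_J), 7, 7)
      list(dh = dh, dJ = (Z + t(Z)) / 2)
    })
    J <- base[[g]]$J + jit$dJ
    diag(J) <- 0
    params <- mem_params(base[[g]]$h + jit$dh, J,
                         network_names = PLANTED_NETWORKS)
    binary <- sample_mem_series(params, config$T_len, seed = ps + 1L,
                                mode = config$series_mode, participant_id = id)
    continuous <- lift_to_continuous(binary, config$noise_sd, seed = ps + 2L)
    walk <- metropolis_walk(build_landscape(params),
                            n_steps = config$truth_steps + 100,
                            seed = ps + 3L, burn_in = 100)
    dyn <- summarize_dynamics(to_state_sequence(walk, canon[[g]]))
    participants[[i]] <- list(id = id, group = g, seed = ps, params = params,
                              binary = binary, continuous = continuous,
                              truth = c(intermediate_freq = dyn$intermediate_freq,
                                        indirect_freq = dyn$indirect_freq,
                                        mean_major_duration = dyn$mean_major_duration))
    truth$participant_id[i] <- id
    truth[i, 3:5] <- participants[[i]]$truth
  }

  td <- groups == "TD"
  score_noise <- withr::with_seed(seeds[n + 1L], stats::rnorm(2 * n))
  ados <- numeric(n); fiq <- numeric(n)
  ados[td] <- planted_score(truth$indirect_freq[td], config$ados_r_td,
                            config$ados_mean["td"], config$ados_sd["td"],
                            score_noise[seq_len(sum(td))])
  ados[!td] <- planted_score(truth$indirect_freq[!td], config$ados_r_asd,
                             config$ados_mean["asd"], config$ados_sd["asd"],
                             score_noise[sum(td) + seq_len(sum(!td))])
  fiq[td] <- planted_score(truth$indirect_freq[td], config$fiq_r_td,
                           config$fiq_mean["td"], config$fiq_sd["td"],
                           score_noise[n + seq_len(sum(td))])
  fiq[!td] <- planted_score(truth$mean_major_duration[!td], config$fiq_r_asd,
                            config$fiq_mean["asd"], config$fiq_sd["asd"],
                            score_noise[n + sum(td) + seq_len(sum(!td))])

  manifest <- data.frame(participant_id = truth$participant_id,
                         group = groups, ados = ados, fiq = fiq,
                         seed = part_seeds, stringsAsFactors = FALSE)
  structure(list(participants = participants, manifest = manifest,
                 config = config, master_seed = master_seed,
                 ground_truth = list(params = base,
                                     grouping = planted_state_grouping(),
                                     truth = truth)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d TD + %d ASD participants, T = %d, mode = %s, master seed %d\n",
              sum(x$manifest$group == "TD"), sum(x$manifest$group == "ASD"),
              x$config$T_len, x$config$series_mode, x$master_seed))
  invisible(x)
}
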