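# Cohort serialization and the end-to-end pipeline driver.

#' Write a cohort to a directory of delimited text files
#'
#' Layout: \code{manifest.json} (participants, group labels, scores, seeds,
#' config), one \code{<id>_continuous.tsv} and one \code{<id>_binary.tsv}
#' per participant (rows = time points, header = network names), and
#' \code{ground_truth.json} when the cohort carries planted ground truth.
#'
#' @param cohort A [build_cohort()] result (or compatible list).
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    utils::write.table(format(p$continuous$values, digits = 17, trim = TRUE),
                       file.path(dir, paste0(p$id, "_continuous.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(p$binary$values,
                       file.path(dir, paste0(p$id, "_binary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(participants = cohort$manifest,
                   master_seed = cohort$master_seed,
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  gt <- cohort$ground_truth
  if (!is.null(gt)) {
    jsonlite::write_json(
      list(params = lapply(gt$params, function(p) list(h = p$h, J = p$J)),
           grouping = gt$grouping, truth = gt$truth),
      file.path(dir, "ground_truth.json"),
      digits = NA, auto_unbox = TRUE, dataframe = "rows")
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Validates the manifest, per-participant file presence, shapes and
#' numeric content; errors name the offending file (and cell, for
#' non-numeric entries).
#'
#' @param dir Cohort directory.
#' @return A \code{cohort_dataset}.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("manifest not found: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  roster <- mf$participants
  stopifnot(is.data.frame(roster), all(c("participant_id", "group") %in% names(roster)))
  read_tsv_matrix <- function(path) {
    if (!file.exists(path)) stop("missing participant file: ", path)
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
    m <- suppressWarnings(apply(as.matrix(d), 2, as.numeric))
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("non-numeric cell in ", path, " at row ", bad[1], ", column ",
           colnames(d)[bad[2]])
    }
    m
  }
  participants <- lapply(seq_len(nrow(roster)), function(i) {
    id <- roster$participant_id[i]
    cont <- read_tsv_matrix(file.path(dir, paste0(id, "_continuous.tsv")))
    bin <- read_tsv_matrix(file.path(dir, paste0(id, "_binary.tsv")))
    if (!identical(dim(cont), dim(bin))) {
      stop("shape mismatch between continuous and binary series for ", id)
    }
    list(id = id, group = roster$group[i],
         seed = if ("seed" %in% names(roster)) roster$seed[i] else NA_integer_,
         binary = binary_ts(bin, network_names = colnames(bin), participant_id = id),
         continuous = network_ts(cont, network_names = colnames(cont), participant_id = id))
  })
  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    nets <- participants[[1]]$binary$network_names
    gt <- list(params = lapply(raw$params, function(p)
                 mem_params(p$h, p$J, network_names = nets)),
               grouping = lapply(raw$grouping, as.integer),
               truth = raw$truth)
  }
  cfg <- mf$config
  if (!is.null(cfg)) class(cfg) <- "cohort_config"
  structure(list(participants = participants,
                 manifest = roster,
                 config = cfg,
                 master_seed = mf$master_seed,
                 ground_truth = gt),
            class = "cohort_dataset")
}

concat_group <- function(cohort, group) {
  mats <- lapply(Filter(function(p) p$group == group, cohort$participants),
                 function(p) p$binary$values)
  if (length(mats) == 0) stop("no participants in group ", group)
  do.call(rbind, mats)
}

codes_of_rows <- function(values) {
  as.integer((values > 0) %*% 2^(0:(ncol(values) - 1)))
}

#' Run the full energy-landscape analysis pipeline on a cohort
#'
#' Per group: concatenate the participants' binary series (roster order),
#' fit the pairwise maximum-entropy model, build the landscape and its
#' minima / disconnectivity tree / basins / brain-state partition, simulate
#' a Metropolis walk and summarize its dynamics, and count the empirical
#' per-participant state frequencies and transitions with the same code
#' path. Then compare groups: basin-size chi-squared with residual tests,
#' t + permutation tests on the per-participant indices, a run-level
#' comparison of simulated major-state durations, behavioural correlations
#' (when scores are present) and functional-segregation statistics.
#'
#' @param cohort A \code{cohort_dataset} (from [build_cohort()] or
#'   [read_cohort()]).
#' @param grouping Minimum grouping passed to [define_brain_states()];
#'   default "auto".
#' @param n_steps,burn_in Metropolis walk settings (defaults 1e5 / 100).
#' @param n_perm Permutations for participant-level group tests.
#' @param n_perm_runs Permutations for the run-level duration test (smaller
#'   default; thousands of runs make the parametric test already stable).
#' @param module_specs List with [module_spec()]s \code{intermediate} and
#'   \code{major} for the segregation analysis; defaults to the planted
#'   parcellation's modules.
#' @param seed Master seed for walks and permutation draws.
#' @param fit_tol,fit_max_iter Passed to [fit_mem()].
#' @return A results bundle (list) with components \code{fits},
#'   \code{landscapes}, \code{partitions}, \code{simulated},
#'   \code{empirical}, \code{group_tests}, \code{behaviour},
#'   \code{coordination} and \code{settings}.
#' @export
run_pipeline <- function(cohort, grouping = "auto",
                         n_steps = 1e5, burn_in = 100,
                         n_perm = 1e4, n_perm_runs = 1000,
                         module_specs = planted_module_specs(),
                         seed, fit_tol = 1e-5, fit_max_iter = 1e6) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (missing(seed)) stop("an explicit seed is required")
  groups <- c("TD", "ASD")

  fits <- lapply(stats::setNames(groups, groups), function(g) {
    fit_mem(concat_group(cohort, g), tol = fit_tol, max_iter = fit_max_iter)
  })
  landscapes <- lapply(fits, function(f) build_landscape(f$params))
  partitions <- list()
  trees <- list()
  basins <- list()
  for (g in groups) {
    ls <- landscapes[[g]]
    minima <- find_local_minima(ls)
    trees[[g]] <- build_disconnectivity_graph(ls, minima)
    basins[[g]] <- assign_basins(ls, minima)
    partitions[[g]] <- define_brain_states(trees[[g]], basins[[g]], grouping)
  }

  simulated <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    codes <- metropolis_walk(landscapes[[g]], n_steps = n_steps,
                             seed = seed + gi, burn_in = burn_in)
    simulated[[g]] <- summarize_dynamics(to_state_sequence(codes, partitions[[g]]))
  }

  # empirical direct counting, one row per participant
  empirical <- do.call(rbind, lapply(cohort$participants, function(p) {
    st <- to_state_sequence(codes_of_rows(p$binary$values),
                            partitions[[p$group]], source = "empirical")
    d <- summarize_dynamics(st)
    data.frame(participant_id = p$id, group = p$group,
               major1 = d$appearance[["major1"]], major2 = d$appearance[["major2"]],
               minor1 = d$appearance[["minor1"]], minor2 = d$appearance[["minor2"]],
               intermediate_freq = d$intermediate_freq,
               direct_freq = d$direct_freq, indirect_freq = d$indirect_freq,
               mean_major_duration = d$mean_major_duration,
               stringsAsFactors = FALSE)
  }))

  td <- empirical$group == "TD"
  cmp <- function(col, s_off) {
    compare_groups(empirical[[col]][td], empirical[[col]][!td],
                   n_perm = n_perm, seed = seed + 100 + s_off)
  }
  # basin-size distribution: counts of patterns per state x group
  state_counts <- vapply(groups, function(g) {
    round(partitions[[g]]$state_sizes * 2^landscapes[[g]]$K)
  }, numeric(4))
  group_tests <- list(
    basin_chi2 = chi2_residual_test(t(state_counts), bonferroni = length(state_counts)),
    appearance = lapply(stats::setNames(c("major1", "major2", "minor1", "minor2", "intermediate_freq"),
                                        c("major1", "major2", "minor1", "minor2", "intermediate")),
                        function(col) cmp(col, match(col, names(empirical)))),
    direct = cmp("direct_freq", 8),
    indirect = cmp("indirect_freq", 9),
    duration_empirical = cmp("mean_major_duration", 10),
    duration_simulated = compare_groups(simulated$ASD$major_runs,
                                        simulated$TD$major_runs,
                                        n_perm = n_perm_runs, seed = seed + 111),
    simulated_transition_chi2 = chi2_residual_test(rbind(
      TD = c(direct = simulated$TD$transitions$direct,
             indirect = simulated$TD$transitions$indirect),
      ASD = c(direct = simulated$ASD$transitions$direct,
              indirect = simulated$ASD$transitions$indirect)), bonferroni = 4)
  )

  behaviour <- NULL
  if (all(c("ados", "fiq") %in% names(cohort$manifest))) {
    mf <- cohort$manifest[match(empirical$participant_id, cohort$manifest$participant_id), ]
    asd <- !td
    # degenerate columns (e.g. no indirect transitions observed in a short
    # scan) yield an NA record instead of aborting the bundle
    safe_cor <- function(x, y, covariates = NULL) {
      tryCatch(correlate(x, y, covariates = covariates),
               error = function(e) list(r = NA_real_, df = NA_integer_,
                                        p = NA_real_, n = length(x),
                                        n_covariates = 0L,
                                        note = conditionMessage(e)))
    }
    behaviour <- list(
      ados_indirect_asd = safe_cor(mf$ados[asd], empirical$indirect_freq[asd]),
      ados_duration_asd = safe_cor(mf$ados[asd], empirical$mean_major_duration[asd]),
      fiq_indirect_td = safe_cor(mf$fiq[td], empirical$indirect_freq[td]),
      fiq_indirect_asd = safe_cor(mf$fiq[asd], empirical$indirect_freq[asd]),
      fiq_duration_asd = safe_cor(mf$fiq[asd], empirical$mean_major_duration[asd]),
      # hierarchy among the three dynamics indices, per group
      partial_interm_indirect = lapply(stats::setNames(groups, groups), function(g) {
        sel <- empirical$group == g
        safe_cor(empirical$intermediate_freq[sel], empirical$indirect_freq[sel],
                 covariates = empirical$mean_major_duration[sel])
      }),
      partial_indirect_duration = lapply(stats::setNames(groups, groups), function(g) {
        sel <- empirical$group == g
        safe_cor(empirical$indirect_freq[sel], empirical$mean_major_duration[sel],
                 covariates = empirical$intermediate_freq[sel])
      })
    )
  }

  coordination <- NULL
  if (!is.null(cohort$participants[[1]]$continuous)) {
    seg <- do.call(rbind, lapply(cohort$participants, function(p) {
      fc <- network_fc(p$continuous)
      zoff <- fc$z; diag(zoff) <- NA
      data.frame(participant_id = p$id, group = p$group,
                 seg_intermediate = segregation_strength(fc, module_specs$intermediate),
                 seg_major = segregation_strength(fc, module_specs$major),
                 within_intermediate = mean(zoff[rbind(
                   upper_pairs(match(module_specs$intermediate$module1, fc$network_names)),
                   upper_pairs(match(module_specs$intermediate$module2, fc$network_names)))]),
                 across_intermediate = mean(zoff[as.matrix(expand.grid(
                   match(module_specs$intermediate$module1, fc$network_names),
                   match(module_specs$intermediate$module2, fc$network_names)))]),
                 stringsAsFactors = FALSE)
    }))
    long <- data.frame(
      z = c(seg$within_intermediate, seg$across_intermediate),
      fc_type = rep(c("within", "across"), each = nrow(seg)),
      group = rep(seg$group, 2))
    coordination <- list(
      table = seg,
      anova_intermediate = two_way_anova(long$z, long$fc_type, long$group),
      seg_group_test = compare_groups(seg$seg_intermediate[seg$group == "TD"],
                                      seg$seg_intermediate[seg$group == "ASD"],
                                      n_perm = n_perm, seed = seed + 200),
      seg_major_group_test = compare_groups(seg$seg_major[seg$group == "ASD"],
                                            seg$seg_major[seg$group == "TD"],
                                            n_perm = n_perm, seed = seed + 201),
      seg_indirect_asd = tryCatch(
        correlate(seg$seg_intermediate[seg$group == "ASD"],
                  empirical$indirect_freq[!td]),
        error = function(e) list(r = NA_real_, p = NA_real_,
                                 note = conditionMessage(e))),
      seg_intermediate_asd = tryCatch(
        correlate(seg$seg_intermediate[seg$group == "ASD"],
                  empirical$intermediate_freq[!td]),
        error = function(e) list(r = NA_real_, p = NA_real_,
                                 note = conditionMessage(e)))
    )
  }

  list(fits = fits, landscapes = landscapes, trees = trees, basins = basins,
       partitions = partitions, simulated = simulated, empirical = empirical,
       group_tests = group_tests, behaviour = behaviour,
       coordination = coordination,
       settings = list(grouping = grouping, n_steps = n_steps,
                       burn_in = burn_in, n_perm = n_perm, seed = seed))
}

#' Individual-level dynamics indices for diagnosis
#'
#' Fits the pairwise model per participant, walks the individual landscape
#' and measures the intermediate-state and indirect-transition frequencies.
#' States are labelled through a reference partition (typically the
#' training cohort's), so indices are comparable across participants even
#' when an individual landscape's own minima differ. A warning is emitted
#' when an individual fit's accuracy falls below 0.9 (individual-level fits
#' are known to be less accurate than group-level ones).
#'
#' @param cohort A \code{cohort_dataset}.
#' @param reference_partition A [define_brain_states()] result used to
#'   label patterns.
#' @param n_steps,burn_in Walk settings.
#' @param seed Master seed; participant i walks with seed + i.
#' @return data.frame with one row per participant: group, intermediate and
#'   indirect frequencies, fit accuracy.
#' @export
individual_indices <- function(cohort, reference_partition,
                               n_steps = 1e5, burn_in = 100, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  out <- lapply(seq_along(cohort$participants), function(i) {
    p <- cohort$participants[[i]]
    fit <- fit_mem(p$binary)
    if (isTRUE(fit$report$accuracy_defined) && fit$report$accuracy < 0.9) {
      warning("individual fit accuracy ", sprintf("%.2f", fit$report$accuracy),
              " for ", p$id, " (individual-level fits are less reliable)")
    }
    codes <- metropolis_walk(build_landscape(fit$params), n_steps = n_steps,
                             seed = seed + i, burn_in = burn_in)
    d <- summarize_dynamics(to_state_sequence(codes, reference_partition))
    data.frame(participant_id = p$id, group = p$group,
               intermediate_freq = d$intermediate_freq,
               indirect_freq = d$indirect_freq,
               accuracy = fit$report$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
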