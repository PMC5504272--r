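#' Network-level functional connectivity
#'
#' Pairwise Pearson correlations between the continuous network time
#' series, plus their Fisher z transforms (z diagonal excluded from any
#' averaging downstream).
#'
#' @param net_ts A [network_ts()] or T x K numeric matrix with T >= 3.
#' @return Object of class \code{fc_matrix}: list with \code{r}, \code{z},
#'   \code{network_names}, \code{participant_id}.
#' @export
network_fc <- function(net_ts) {
  vals <- as_values(net_ts)
  if (nrow(vals) < 3) stop("need at least 3 time points")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant network signal: ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(vals)
  structure(list(r = r, z = fisher_z(r),
                 network_names = colnames(vals),
                 participant_id = if (inherits(net_ts, "network_ts")) net_ts$participant_id else NA_character_),
            class = "fc_matrix")
}

#' Two-module specification for segregation analysis
#'
#' @param module1,module2 Disjoint, non-empty character vectors of network
#'   names; their union must cover all networks under analysis.
#' @param name Optional label (e.g. "intermediate-state modules").
#' @export
module_spec <- function(module1, module2, name = NULL) {
  stopifnot(length(module1) >= 1, length(module2) >= 1)
  if (length(intersect(module1, module2)) > 0) stop("modules must be disjoint")
  structure(list(module1 = module1, module2 = module2, name = name),
            class = "module_spec")
}

#' Functional segregation strength between two network modules
#'
#' Mean Fisher-z connectivity over the within-module network pairs (both
#' modules' internal pairs pooled, unweighted) minus the mean over the
#' across-module pairs. Larger values mean the two modules are more
#' functionally segregated.
#'
#' @param fc An [network_fc()] result.
#' @param spec A [module_spec()] covering all networks in \code{fc}.
#' @return Scalar segregation strength (z units).
#' @export
segregation_strength <- function(fc, spec) {
  stopifnot(inherits(fc, "fc_matrix"), inherits(spec, "module_spec"))
  nets <- fc$network_names
  if (!setequal(nets, c(spec$module1, spec$module2))) {
    stop("module spec must cover exactly the networks in the FC matrix")
  }
  z <- fc$z
  idx1 <- match(spec$module1, nets)
  idx2 <- match(spec$module2, nets)
  within_pairs <- rbind(upper_pairs(idx1), upper_pairs(idx2))
  if (nrow(within_pairs) == 0) {
    stop("no within-module pairs: both modules have a single network")
  }
  across_pairs <- as.matrix(expand.grid(idx1, idx2))
  mean(z[within_pairs]) - mean(z[across_pairs])
}

upper_pairs <- function(idx) {
  if (length(idx) < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(idx, 2))
}
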