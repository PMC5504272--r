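#' Construct a continuous network time-series object
#'
#' A thin container for a T x K matrix of per-network continuous activity
#' (e.g. network-averaged BOLD signal), with network names and a participant
#' identifier. Column order is fixed and defines the bit order of pattern
#' codes downstream.
#'
#' @param values T x K numeric matrix, rows = time points.
#' @param network_names Character vector of K column labels.
#' @param participant_id Identifier for the participant (scalar).
#' @return An object of class \code{network_ts}.
#' @export
network_ts <- function(values, network_names = colnames(values),
                       participant_id = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 time points")
  if (ncol(values) < 2) stop("need at least 2 networks")
  if (anyNA(values) || !is.numeric(values)) stop("values must be numeric with no missing entries")
  if (is.null(network_names)) network_names <- paste0("N", seq_len(ncol(values)))
  stopifnot(length(network_names) == ncol(values))
  colnames(values) <- network_names
  structure(list(values = values, network_names = network_names,
                 participant_id = participant_id),
            class = "network_ts")
}

#' @export
print.network_ts <- function(x, ...) {
  cat(sprintf("<network_ts> participant %s: %d time points x %d networks (%s)\n",
              x$participant_id, nrow(x$values), ncol(x$values),
              paste(x$network_names, collapse = ", ")))
  invisible(x)
}

#' Construct a binary (+1/-1) network time-series object
#'
#' @param values T x K matrix with every entry exactly -1 or +1 (+1 active).
#' @inheritParams network_ts
#' @return An object of class \code{binary_ts}.
#' @export
binary_ts <- function(values, network_names = colnames(values),
                      participant_id = NA_character_) {
  values <- as.matrix(values)
  if (!all(values %in% c(-1, 1))) stop("every entry must be exactly -1 or +1")
  if (is.null(network_names)) network_names <- paste0("N", seq_len(ncol(values)))
  stopifnot(length(network_names) == ncol(values))
  colnames(values) <- network_names
  structure(list(values = values, network_names = network_names,
                 participant_id = participant_id),
            class = "binary_ts")
}

#' @export
print.binary_ts <- function(x, ...) {
  cat(sprintf("<binary_ts> participant %s: %d time points x %d networks, %.1f%% active\n",
              x$participant_id, nrow(x$values), ncol(x$values),
              100 * mean(x$values > 0)))
  invisible(x)
}

as_values <- function(x) {
  if (inherits(x, c("network_ts", "binary_ts"))) x$values else as.matrix(x)
}

#' Average ROI time series within networks
#'
#' Collapses a T x R matrix of region-of-interest (ROI) signals to a T x K
#' matrix of per-network signals by taking, at every time point, the
#' arithmetic mean over the ROIs assigned to each network.
#'
#' @param roi_ts T x R numeric matrix of ROI time series; columns named by
#'   ROI id.
#' @param assignment Data frame with columns \code{roi_id} and
#'   \code{network}; every ROI column of \code{roi_ts} must appear, and
#'   every network must own at least one ROI.
#' @param participant_id Passed through to the result.
#' @return A [network_ts()] whose columns follow the order in which networks
#'   first appear in \code{assignment}.
#' @export
average_network_activity <- function(roi_ts, assignment,
                                     participant_id = NA_character_) {
  roi_ts <- as.matrix(roi_ts)
  stopifnot(is.data.frame(assignment),
            all(c("roi_id", "network") %in% names(assignment)))
  rois <- colnames(roi_ts)
  if (is.null(rois)) stop("roi_ts must have ROI ids as column names")
  missing <- setdiff(rois, assignment$roi_id)
  if (length(missing) > 0) {
    stop("ROI(s) not present in the assignment table: ",
         paste(missing, collapse = ", "))
  }
  networks <- unique(assignment$network)
  out <- vapply(networks, function(net) {
    members <- intersect(assignment$roi_id[assignment$network == net], rois)
    if (length(members) == 0) {
      stop("network '", net, "' has no ROI columns in roi_ts")
    }
    rowMeans(roi_ts[, members, drop = FALSE])
  }, numeric(nrow(roi_ts)))
  network_ts(out, network_names = networks, participant_id = participant_id)
}

#' Binarize network activity at its temporal mean
#'
#' For each network (column) independently, time points strictly above that
#' network's temporal mean become +1 (active) and all others -1 (inactive).
#' A value exactly at the mean maps to -1; the tie is measure-zero for
#' continuous signals but the rule must be deterministic. Binarization is
#' per participant and per network, before any concatenation across
#' participants, and makes active/inactive counts approximately balanced for
#' non-degenerate signals.
#'
#' @param net_ts A [network_ts()] or plain T x K numeric matrix.
#' @return A [binary_ts()] with the same shape metadata. Constant columns
#'   produce all -1 plus a warning naming the degenerate network.
#' @export
binarize_mean_threshold <- function(net_ts) {
  vals <- as_values(net_ts)
  if (nrow(vals) < 2) stop("need at least 2 time points")
  mu <- colMeans(vals)
  const <- apply(vals, 2, function(col) all(col == col[1]))
  if (any(const)) {
    warning("constant (degenerate) network signal: ",
            paste(colnames(vals)[const], collapse = ", "),
            "; binarized to all -1")
  }
  bin <- ifelse(sweep(vals, 2, mu, `-`) > 0, 1, -1)
  binary_ts(bin,
            network_names = if (inherits(net_ts, "network_ts")) net_ts$network_names else colnames(vals),
            participant_id = if (inherits(net_ts, "network_ts")) net_ts$participant_id else NA_character_)
}

#' Similarity between two binary activity series
#'
#' The fraction of time points at which two equal-length binary series take
#' the same state. Internally the +/-1 coding is converted to 1/0 and the
#' similarity computed as \eqn{1 - \mathrm{Hamming}(X_i, X_j)/N_T}.
#'
#' @param x,y Vectors of equal length with entries -1/+1 (or 1/0).
#' @return Fraction in \code{[0, 1]}.
#' @export
#' @examples
#' binary_similarity(c(1, 1, -1), c(1, -1, -1))  # 2/3
binary_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ: ", length(x), " vs ", length(y))
  xb <- as.integer(x > 0)
  yb <- as.integer(y > 0)
  mean(xb == yb)
}

#' Fisher z-transform with clamping
#'
#' atanh of a correlation with \code{|r|} clamped to \code{1 - 1e-12} so
#' that degenerate perfect correlations stay finite.
#'
#' @param r Correlation value(s).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' Split default-mode-network ROIs by seed correlation
#'
#' Assigns each DMN ROI to a vmPFC-led or PCC-led subdivision: per
#' participant, the ROI's Pearson correlation with each seed series is
#' computed, Fisher z-transformed, and averaged across participants; the ROI
#' joins the subdivision whose average z is larger (ties go to PCC via the
#' strict > rule).
#'
#' @param roi_ts_list List (one per participant) of T x R matrices with ROI
#'   ids as column names.
#' @param dmn_rois Character vector of ROI ids to classify.
#' @param vmpfc_series,pcc_series Lists (one per participant) of seed time
#'   series vectors aligned with the rows of the matrices.
#' @return List with character vectors \code{vmpfc_dmn} and \code{pcc_dmn};
#'   disjoint, union equal to \code{dmn_rois}.
#' @export
split_dmn_by_seed <- function(roi_ts_list, dmn_rois, vmpfc_series, pcc_series) {
  stopifnot(length(roi_ts_list) >= 1,
            length(vmpfc_series) == length(roi_ts_list),
            length(pcc_series) == length(roi_ts_list))
  zbar <- function(seed_series) {
    z <- vapply(seq_along(roi_ts_list), function(p) {
      ts <- as.matrix(roi_ts_list[[p]])
      seed <- seed_series[[p]]
      if (stats::sd(seed) == 0) stop("zero-variance seed series for participant ", p)
      vapply(dmn_rois, function(roi) {
        col <- ts[, roi]
        if (stats::sd(col) == 0) stop("zero-variance ROI series: ", roi)
        fisher_z(stats::cor(col, seed))
      }, numeric(1))
    }, numeric(length(dmn_rois)))
    rowMeans(matrix(z, nrow = length(dmn_rois)))
  }
  z_vmpfc <- zbar(vmpfc_series)
  z_pcc <- zbar(pcc_series)
  vm <- dmn_rois[z_vmpfc > z_pcc]
  list(vmpfc_dmn = vm, pcc_dmn = setdiff(dmn_rois, vm))
}
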