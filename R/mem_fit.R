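#' Pairwise maximum-entropy model parameters
#'
#' Container for the basal activities \code{h} (length K) and symmetric
#' pairwise interactions \code{J} (K x K, zero diagonal) of a pairwise
#' maximum-entropy (Ising) model over binary +/-1 activity vectors. The
#' energy convention is
#' \deqn{E(V) = -\sum_i h_i \sigma_i(V) - \tfrac{1}{2}\sum_{i \ne j} J_{ij}
#'   \sigma_i(V)\sigma_j(V)}
#' with appearance probability \eqn{P(V) \propto e^{-E(V)}}; the 1/2 only
#' rescales J and all probability-level outputs are convention-invariant.
#'
#' @param h Numeric vector of basal activities (dimensionless).
#' @param J Symmetric numeric matrix of pairwise interactions with exactly
#'   zero diagonal.
#' @param network_names Optional labels for the K networks.
#' @return Object of class \code{mem_params}.
#' @export
mem_params <- function(h, J, network_names = NULL) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  K <- length(h)
  stopifnot(nrow(J) == K, ncol(J) == K)
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-10))) stop("J must be symmetric")
  if (any(diag(J) != 0)) stop("J must have an exactly zero diagonal")
  J <- (J + t(J)) / 2
  if (is.null(network_names)) network_names <- paste0("N", seq_len(K))
  structure(list(h = h, J = J, K = K, network_names = network_names),
            class = "mem_params")
}

#' @export
print.mem_params <- function(x, ...) {
  cat(sprintf("<mem_params> K = %d; |h| in [%.3f, %.3f]; |J| in [0, %.3f]\n",
              x$K, min(abs(x$h)), max(abs(x$h)), max(abs(x$J))))
  invisible(x)
}

#' Empirical first and second moments of a binary time series
#'
#' Temporal means \eqn{\langle\sigma_i\rangle} and
#' \eqn{\langle\sigma_i\sigma_j\rangle} of the +/-1 activities; these are the
#' sufficient statistics that the pairwise maximum-entropy fit matches.
#'
#' @param bts A [binary_ts()] or +/-1 matrix (rows = time points).
#' @return List with \code{m1} (length-K vector) and \code{m2} (symmetric
#'   K x K matrix with unit diagonal).
#' @export
empirical_moments <- function(bts) {
  x <- as_values(bts)
  if (!all(x %in% c(-1, 1))) stop("series must be +/-1 coded")
  list(m1 = colMeans(x), m2 = crossprod(x) / nrow(x))
}

#' Energy of one activity pattern
#'
#' @param v Pattern vector in \{-1, +1\}^K.
#' @param params A [mem_params()].
#' @return Scalar energy; lower energy means higher appearance probability.
#' @export
state_energy <- function(v, params) {
  stopifnot(inherits(params, "mem_params"), length(v) == params$K)
  if (!all(v %in% c(-1, 1))) stop("pattern entries must be -1 or +1")
  -sum(params$h * v) - 0.5 * sum(v * (params$J %*% v))
}

# Energies of all 2^K patterns at once (code order). S may be passed to
# avoid re-enumeration in inner loops.
all_energies <- function(params, S = all_patterns(params$K)) {
  -as.vector(S %*% params$h) - 0.5 * rowSums((S %*% params$J) * S)
}

#' Boltzmann distribution over all activity patterns
#'
#' Exhaustively enumerates the \code{2^K} patterns and returns their
#' appearance probabilities \eqn{P(V) = e^{-E(V)} / \sum_W e^{-E(W)}}.
#' Energies are shifted by their minimum before exponentiation, so the
#' result is invariant to any constant energy offset and numerically safe.
#'
#' @param params A [mem_params()]; K must be within the enumeration cap.
#' @return Numeric vector of length \code{2^K}, indexed by pattern code + 1,
#'   summing to 1.
#' @export
boltzmann_distribution <- function(params) {
  check_enumeration_cap(params$K)
  E <- all_energies(params)
  p <- exp(-(E - min(E)))
  p / sum(p)
}

# Model moments under the Boltzmann distribution (exact enumeration).
model_moments <- function(params, S = all_patterns(params$K)) {
  E <- all_energies(params, S)
  p <- exp(-(E - min(E)))
  p <- p / sum(p)
  list(m1 = as.vector(crossprod(S, p)), m2 = crossprod(S, p * S))
}

#' Fit a pairwise maximum-entropy model by moment-matching gradient ascent
#'
#' Adjusts \code{h} and \code{J} from zero initialization until the model
#' moments (computed by exact enumeration over the \code{2^K} patterns)
#' match the empirical moments of the data:
#' \code{h <- h + eta * (m1_emp - m1_mod)},
#' \code{J <- J + eta * (m2_emp - m2_mod)} with \code{J} kept symmetric and
#' zero-diagonal. This is gradient ascent on the (concave) log-likelihood,
#' so the fixed point is unique and the run is deterministic.
#'
#' @param bts A [binary_ts()] or +/-1 matrix; for a group-level fit pass the
#'   per-participant series concatenated by row.
#' @param learning_rate Step size \eqn{\eta}; default \code{0.2} (applied as
#'   \code{0.2 / K} internally so the step is stable across K).
#' @param tol Convergence tolerance on the maximum absolute moment
#'   discrepancy.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return List with \code{params} ([mem_params()]) and \code{report}
#'   (a \code{fit_report} from [fit_accuracy()] augmented with
#'   \code{n_iter}, \code{converged} and \code{max_discrepancy}).
#' @export
fit_mem <- function(bts, learning_rate = 0.2, tol = 1e-5, max_iter = 1e6) {
  x <- as_values(bts)
  K <- ncol(x)
  check_enumeration_cap(K)
  if (nrow(x) < 2^K) {
    warning("T = ", nrow(x), " < 2^K = ", 2^K,
            "; appearance probabilities will be noisy")
  }
  both <- apply(x, 2, function(col) length(unique(col)) == 2)
  if (!all(both)) {
    stop("network(s) never change state: ",
         paste(which(!both), collapse = ", "))
  }
  emp <- empirical_moments(x)
  S <- all_patterns(K)
  eta <- learning_rate / K
  h <- numeric(K)
  J <- matrix(0, K, K)
  maxdisc <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    E <- -as.vector(S %*% h) - 0.5 * rowSums((S %*% J) * S)
    p <- exp(-(E - min(E)))
    p <- p / sum(p)
    m1m <- as.vector(crossprod(S, p))
    m2m <- crossprod(S, p * S)
    g1 <- emp$m1 - m1m
    g2 <- emp$m2 - m2m
    diag(g2) <- 0
    maxdisc <- max(abs(g1), abs(g2))
    if (maxdisc < tol) break
    h <- h + eta * g1
    J <- J + eta * g2
  }
  nm <- if (inherits(bts, "binary_ts")) bts$network_names else colnames(x)
  params <- mem_params(h, J, network_names = nm)
  report <- fit_accuracy(params, x)
  report$n_iter <- iter
  report$converged <- maxdisc < tol
  report$max_discrepancy <- maxdisc
  list(params = params, report = report)
}

#' Goodness of fit of a pairwise maximum-entropy model
#'
#' Two accuracy measures against the data the model was fitted to:
#' the Pearson correlation \code{r} between model and empirical appearance
#' probabilities over all \code{2^K} patterns, and the proportion of
#' Kullback-Leibler divergence removed by the pairwise (2nd-order) model
#' relative to an independent-network (1st-order) model:
#' \code{accuracy = (D1 - D2) / D1}, where \code{D2 = KL(empirical ||
#' pairwise model)} and \code{D1 = KL(empirical || independent model)}.
#' The 1st-order model fits only \eqn{\langle\sigma_i\rangle} (J = 0).
#' KL terms with zero empirical probability contribute 0.
#'
#' @param params A [mem_params()].
#' @param bts The fitted data ([binary_ts()] or +/-1 matrix).
#' @return Object of class \code{fit_report}: list with \code{r},
#'   \code{accuracy}, \code{d1}, \code{d2} and
#'   \code{accuracy_defined} (FALSE when \code{D1} is numerically 0, i.e.
#'   the data carry no pairwise structure to explain).
#' @export
fit_accuracy <- function(params, bts) {
  x <- as_values(bts)
  K <- params$K
  stopifnot(ncol(x) == K)
  codes <- as.integer((x > 0) %*% 2^(0:(K - 1)))
  p_emp <- tabulate(codes + 1L, 2^K) / nrow(x)
  p_mod <- boltzmann_distribution(params)
  # independent-network model: tanh(h_i) = <sigma_i>, J = 0 (clamped atanh)
  m1 <- colMeans(x)
  p_ind <- boltzmann_distribution(
    mem_params(fisher_z(m1), matrix(0, K, K)))
  kl <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * log(p[nz] / q[nz]))
  }
  d2 <- kl(p_emp, p_mod)
  d1 <- kl(p_emp, p_ind)
  defined <- d1 > 1e-12
  # r is undefined for a perfectly flat probability vector (e.g. uniform data)
  r <- if (stats::sd(p_emp) == 0 || stats::sd(p_mod) == 0) NA_real_
       else stats::cor(p_emp, p_mod)
  structure(list(
    r = r,
    accuracy = if (defined) (d1 - d2) / d1 else NA_real_,
    accuracy_defined = defined,
    d1 = d1, d2 = d2,
    n_iter = NA_integer_, converged = NA, max_discrepancy = NA_real_
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> r = %.4f; accuracy = %s; converged = %s (%s iter, max disc %.2g)\n",
              x$r,
              if (isTRUE(x$accuracy_defined)) sprintf("%.4f", x$accuracy) else "undefined (D1 ~ 0)",
              x$converged, format(x$n_iter), x$max_discrepancy))
  invisible(x)
}

#' Serialize model parameters to JSON
#'
#' Writes \code{h}, \code{J}, network names and the energy-convention tag to
#' a JSON file readable by [read_mem_params()].
#'
#' @param params A [mem_params()].
#' @param path Output file path.
#' @param metadata Optional named list stored verbatim (e.g. fit settings).
#' @export
write_mem_params <- function(params, path, metadata = NULL) {
  obj <- list(h = params$h, J = params$J,
              network_names = params$network_names,
              convention = "E = -sum h_i s_i - 1/2 sum_{i!=j} J_ij s_i s_j; P ~ exp(-E)",
              metadata = metadata)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mem_params
#' @export
read_mem_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem_params(obj$h, obj$J, network_names = obj$network_names)
}

#' Write an appearance-probability table as TSV
#'
#' One row per pattern: code, bit string and probability.
#'
#' @param p Probability vector over the \code{2^K} patterns (e.g. from
#'   [boltzmann_distribution()]) or a [mem_params()] object.
#' @param path Output file path.
#' @export
write_probability_table <- function(p, path) {
  if (inherits(p, "mem_params")) p <- boltzmann_distribution(p)
  K <- round(log2(length(p)))
  stopifnot(length(p) == 2^K)
  S <- all_patterns(K)
  df <- data.frame(
    code = 0:(2^K - 1),
    pattern = apply(S, 1, function(r) paste(ifelse(r > 0, "1", "0"), collapse = "")),
    probability = p
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
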