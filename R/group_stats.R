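#' Two-sample group comparison with permutation confirmation
#'
#' Pooled-variance two-sample t test (the reported df is n1 + n2 - 2),
#' a label-shuffling permutation test with the two-sided rule
#' p = (#\{|t*| >= |t|\} + 1) / (n_perm + 1), and Cohen's d with pooled
#' standard deviation.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param n_perm Number of random permutations (default 1e4).
#' @param seed Seed for the permutation draw (mandatory when n_perm > 0).
#' @return Object of class \code{group_comparison}: list with \code{t},
#'   \code{df}, \code{p}, \code{p_perm}, \code{cohen_d}, group means, sds
#'   and sizes.
#' @export
compare_groups <- function(a, b, n_perm = 1e4, seed = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 == 0) stop("zero pooled variance")
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("a seed is required for the permutation test")
    pooled <- c(a, b)
    p_perm <- withr::with_seed(seed, {
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n1 + n2, n1)
        pa <- pooled[idx]; pb <- pooled[-idx]
        s2 <- ((n1 - 1) * stats::var(pa) + (n2 - 1) * stats::var(pb)) / df
        tp <- if (s2 == 0) 0 else (mean(pa) - mean(pb)) / sqrt(s2 * (1 / n1 + 1 / n2))
        if (abs(tp) >= abs(tstat)) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_perm + 1)
    })
  }
  structure(list(t = tstat, df = df, p = p, p_perm = p_perm, cohen_d = d,
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = n1, n_b = n2, n_perm = n_perm, seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t(%d) = %.3f, p = %.4g (perm p = %.4g), Cohen's d = %.2f\n",
              x$df, x$t, x$p, x$p_perm, x$cohen_d))
  invisible(x)
}

#' Chi-squared test with post hoc adjusted standardized residuals
#'
#' Pearson chi-squared test of independence on a count table, followed by
#' per-cell adjusted standardized residuals
#' \eqn{Z = (O - E) / \sqrt{E (1 - p_{row}) (1 - p_{col})}} and
#' Bonferroni-corrected significance flags.
#'
#' @param counts Numeric matrix of counts with positive marginals.
#' @param alpha Family-wise error rate (default 0.05).
#' @param bonferroni Correction factor; defaults to the number of cells.
#' @return List with \code{chi2}, \code{df}, \code{p}, \code{residuals}
#'   (Z matrix), \code{significant} (logical matrix at corrected alpha) and
#'   \code{expected}.
#' @export
chi2_residual_test <- function(counts, alpha = 0.05, bonferroni = length(counts)) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in the count table")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected counts must be > 0")
  z <- ct$stdres
  pz <- 2 * stats::pnorm(-abs(z))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, residuals = z,
       significant = pz < alpha / bonferroni,
       expected = ct$expected)
}

#' Pearson or partial correlation with a no-correlation test
#'
#' Without covariates: plain Pearson r with a t-based two-sided p on
#' n - 2 df. With covariates: the partial correlation of x and y given the
#' covariates, computed as the Pearson correlation of the residuals of x
#' and y after linear regression on the covariates, tested on
#' n - 2 - #covariates df.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric vector, matrix or data.frame of
#'   control variables.
#' @return List with \code{r}, \code{df}, \code{p}, \code{n},
#'   \code{n_covariates}.
#' @export
correlate <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  k <- 0L
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    stopifnot(nrow(cv) == length(x))
    k <- ncol(cv)
    x <- stats::residuals(stats::lm(x ~ cv))
    y <- stats::residuals(stats::lm(y ~ cv))
  }
  n <- length(x)
  if (n < 3 + k) stop("need at least 3 + #covariates observations")
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tstat), df), n = n,
       n_covariates = k)
}

#' Two-way factorial ANOVA (fixed effects, Type II sums of squares)
#'
#' Used for the (FC type: within/across-module) x (group) design; Type II
#' sums of squares are reported (the designs here are balanced or nearly
#' balanced, where Type I and Type II agree or nearly agree).
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (coerced) of the two crossed factors.
#' @return data.frame with rows A, B, A:B and columns \code{F}, \code{df1},
#'   \code{df2}, \code{p}.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  stopifnot(length(values) == length(fa), length(fa) == length(fb),
            nlevels(fa) >= 2, nlevels(fb) >= 2)
  if (any(table(fa, fb) < 2)) stop("every cell needs at least 2 observations")
  fit <- stats::lm(values ~ fa * fb)
  an <- car::Anova(fit, type = 2)
  df2 <- an["Residuals", "Df"]
  rows <- c("fa", "fb", "fa:fb")
  out <- data.frame(
    effect = c("A", "B", "A:B"),
    F = an[rows, "F value"],
    df1 = an[rows, "Df"],
    df2 = df2,
    p = an[rows, "Pr(>F)"]
  )
  rownames(out) <- NULL
  out
}
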