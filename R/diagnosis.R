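#' Univariate diagnostic cutoff from the training cohorts
#'
#' The cutoff is ((minimum value in the TD group) + (maximum value in the
#' ASD group)) / 2 -- the midpoint between the two group extremes that face
#' each other when the index is lower in ASD. The classification direction
#' is derived from the training means rather than hard-coded: when the ASD
#' mean is below the TD mean, values below the threshold are classified
#' ASD, and conversely.
#'
#' @param td_values,asd_values Training index values per group (non-empty).
#' @return Object of class \code{dynamics_classifier} with \code{kind =
#'   "univariate"}, \code{threshold} and \code{direction} ("below" = ASD
#'   below threshold).
#' @export
univariate_cutoff <- function(td_values, asd_values) {
  stopifnot(length(td_values) >= 1, length(asd_values) >= 1)
  thr <- (min(td_values) + max(asd_values)) / 2
  structure(list(kind = "univariate",
                 threshold = thr,
                 direction = if (mean(asd_values) < mean(td_values)) "below" else "above",
                 train_fingerprint = train_fingerprint(c(td_values, asd_values))),
            class = "dynamics_classifier")
}

#' Bivariate linear maximum-margin classifier
#'
#' Fits a soft-margin linear support vector machine on two dynamics indices
#' (intermediate-state frequency and indirect-transition frequency in the
#' reference analysis). Features are used on their native scale (both are
#' percentages of comparable magnitude); regularization is fixed at
#' \code{cost = 1} by default and the fit is deterministic for fixed inputs.
#'
#' @param features n x 2 numeric matrix.
#' @param labels Vector with exactly two classes, "TD" and "ASD".
#' @param cost Soft-margin cost parameter.
#' @return Object of class \code{dynamics_classifier} with \code{kind =
#'   "bivariate"}, \code{weights}, \code{bias}; ASD side derived from the
#'   training labels. Decision value w.x + b > 0 classifies ASD.
#' @export
bivariate_boundary <- function(features, labels, cost = 1) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == 2, nrow(features) == length(labels))
  labels <- as.character(labels)
  if (!setequal(unique(labels), c("TD", "ASD"))) {
    stop("both classes (TD, ASD) must be present")
  }
  y <- factor(labels, levels = c("TD", "ASD"))
  fit <- e1071::svm(x = features, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients decision values by factor level order; flip so that
  # positive decision value = ASD
  dv <- features %*% w + b
  if (mean(dv[labels == "ASD"]) < mean(dv[labels == "TD"])) {
    w <- -w; b <- -b
  }
  if (all(w == 0)) stop("degenerate boundary: zero weight vector")
  structure(list(kind = "bivariate", weights = w, bias = b, cost = cost,
                 train_fingerprint = train_fingerprint(features)),
            class = "dynamics_classifier")
}

train_fingerprint <- function(x) {
  paste(format(as.vector(as.matrix(x)), digits = 15), collapse = "|")
}

#' Predict group membership from dynamics indices
#'
#' @param object A [univariate_cutoff()] or [bivariate_boundary()] result.
#' @param newdata Numeric vector (univariate) or n x 2 matrix (bivariate).
#' @param ... Unused.
#' @return Character vector of "TD"/"ASD".
#' @export
predict.dynamics_classifier <- function(object, newdata, ...) {
  if (object$kind == "univariate") {
    v <- as.numeric(newdata)
    asd <- if (object$direction == "below") v < object$threshold else v > object$threshold
  } else {
    x <- as.matrix(newdata)
    stopifnot(ncol(x) == 2)
    asd <- as.vector(x %*% object$weights + object$bias) > 0
  }
  ifelse(asd, "ASD", "TD")
}

#' Sensitivity and specificity of a diagnostic classifier
#'
#' ASD is the positive class: sensitivity = TP / (TP + FN) over the ASD
#' test participants, specificity = TN / (TN + FP) over the TD test
#' participants. To mirror an external-validation design, evaluation on the
#' classifier's own training data is refused unless
#' \code{allow_training = TRUE}.
#'
#' @param clf A \code{dynamics_classifier}.
#' @param features Test features (vector or n x 2 matrix).
#' @param labels True labels ("TD"/"ASD").
#' @param allow_training Override the train/test separation guard.
#' @return List with \code{sensitivity}, \code{specificity} (NA with a
#'   flag when a class is absent), \code{predictions} and \code{n}.
#' @export
evaluate_classifier <- function(clf, features, labels, allow_training = FALSE) {
  stopifnot(inherits(clf, "dynamics_classifier"))
  labels <- as.character(labels)
  if (!allow_training &&
      identical(train_fingerprint(features), clf$train_fingerprint)) {
    stop("refusing to evaluate on the training cohort; pass allow_training = TRUE to override")
  }
  pred <- predict(clf, features)
  stopifnot(length(pred) == length(labels))
  asd <- labels == "ASD"
  td <- labels == "TD"
  list(
    sensitivity = if (any(asd)) mean(pred[asd] == "ASD") else NA_real_,
    specificity = if (any(td)) mean(pred[td] == "TD") else NA_real_,
    sensitivity_defined = any(asd),
    specificity_defined = any(td),
    predictions = pred,
    n = length(labels)
  )
}
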