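# Parametric binormal ROC model on the log-SRAR scale.
#
# Both groups' log-transformed marker values are modelled as Gaussian;
# sensitivity, specificity, the ROC curve and the AUC then have closed
# forms. Group 1 (positive) is the non-length-dependent group with the
# higher SRAR; group 0 (negative) is the length-dependent group. The test
# is positive when SRAR > threshold.

#' Fit the two-group binormal model on the log scale
#'
#' Per-group Gaussian fit of the log-transformed marker: sample mean and
#' sample SD (n - 1 denominator) of `log(values)` within each group —
#' normal-theory binormal fitting, deterministic and invariant under
#' within-group relabeling.
#'
#' @param values Positive marker values (SRAR).
#' @param labels Binary group indicators, coercible to 0/1 or logical:
#'   1/`TRUE` = positive (non-length-dependent) group, 0/`FALSE` =
#'   negative (length-dependent) group.
#'
#' @return An object of class `"binormal_model"`: list with `mu0`,
#'   `sigma0`, `mu1`, `sigma1` (log-scale means and SDs) and group sizes
#'   `n0`, `n1`.
#'
#' @examples
#' set.seed(1)
#' v <- c(rlnorm(30, log(0.17), 0.48), rlnorm(60, log(0.74), 0.51))
#' fit_binormal(v, rep(c(0, 1), c(30, 60)))
#'
#' @export
fit_binormal <- function(values, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1 or logical)")
  if (length(values) != length(labels))
    stop("values and labels must have the same length")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (any(values <= 0))
    stop("all marker values must be positive (the model is log-scale)")
  x0 <- log(values[labels == 0])
  x1 <- log(values[labels == 1])
  if (length(x0) < 2L || length(x1) < 2L)
    stop("need at least 2 observations per group")
  s0 <- stats::sd(x0); s1 <- stats::sd(x1)
  if (s0 == 0 || s1 == 0)
    stop("zero within-group variance: binormal model is degenerate")
  structure(
    list(mu0 = mean(x0), sigma0 = s0,
         mu1 = mean(x1), sigma1 = s1,
         n0 = length(x0), n1 = length(x1)),
    class = "binormal_model"
  )
}

#' Construct a binormal model from known parameters
#'
#' @param mu0,sigma0 Log-scale mean and SD of the negative group.
#' @param mu1,sigma1 Log-scale mean and SD of the positive group.
#' @param n0,n1 Nominal group sizes (metadata only).
#' @return An object of class `"binormal_model"`.
#' @export
binormal_model <- function(mu0, sigma0, mu1, sigma1, n0 = 2L, n1 = 2L) {
  if (sigma0 <= 0 || sigma1 <= 0) stop("sigmas must be positive")
  if (n0 < 2L || n1 < 2L) stop("group sizes must be >= 2")
  structure(
    list(mu0 = mu0, sigma0 = sigma0, mu1 = mu1, sigma1 = sigma1,
         n0 = as.integer(n0), n1 = as.integer(n1)),
    class = "binormal_model"
  )
}

#' @export
print.binormal_model <- function(x, ...) {
  cat("binormal model (log scale)\n")
  cat(sprintf("  negative group: mu0 = %.4f, sigma0 = %.4f (n = %d)\n",
              x$mu0, x$sigma0, x$n0))
  cat(sprintf("  positive group: mu1 = %.4f, sigma1 = %.4f (n = %d)\n",
              x$mu1, x$sigma1, x$n1))
  cat(sprintf("  AUC = %.4f\n", binormal_auc(x)))
  invisible(x)
}

#' Parametric sensitivity and specificity at a threshold
#'
#' With the convention that SRAR > threshold is a positive test for the
#' non-length-dependent group:
#' \deqn{Se(t) = \Phi\!\left(\frac{\mu_1 - \ln t}{\sigma_1}\right), \qquad
#'       Sp(t) = \Phi\!\left(\frac{\ln t - \mu_0}{\sigma_0}\right)}
#'
#' @param model A `"binormal_model"`.
#' @param threshold Positive threshold(s); vectorized.
#' @return A data frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
parametric_se_sp <- function(model, threshold) {
  stopifnot(inherits(model, "binormal_model"))
  if (any(threshold <= 0)) stop("threshold must be positive")
  x <- log(threshold)
  data.frame(
    threshold = threshold,
    sensitivity = stats::pnorm((model$mu1 - x) / model$sigma1),
    specificity = stats::pnorm((x - model$mu0) / model$sigma0)
  )
}

#' Closed-form binormal AUC
#'
#' \deqn{AUC = \Phi\!\left(\frac{\mu_1 - \mu_0}
#'   {\sqrt{\sigma_0^2 + \sigma_1^2}}\right)}
#' which equals \eqn{P(X_1 > X_0)} for independent draws from the two
#' fitted log-normal marker distributions.
#'
#' @param model A `"binormal_model"`.
#' @return Area under the parametric ROC curve, in `[0, 1]`.
#' @export
binormal_auc <- function(model) {
  stopifnot(inherits(model, "binormal_model"))
  stats::pnorm((model$mu1 - model$mu0) /
                 sqrt(model$sigma0^2 + model$sigma1^2))
}

#' Evaluate the parametric ROC curve on a threshold grid
#'
#' Thresholds are log-spaced over the envelope
#' \eqn{[\min(\mu_0 - 4\sigma_0, \mu_1 - 4\sigma_1),
#'       \max(\mu_0 + 4\sigma_0, \mu_1 + 4\sigma_1)]}
#' so the curve runs from near (1, 1) to near (0, 0).
#'
#' @param model A `"binormal_model"`.
#' @param n_points Number of grid points (>= 2).
#' @return An object of class `"roc_curve"`: a data frame with
#'   `threshold`, `fpr` (1 - specificity), `tpr` (sensitivity), and an
#'   `auc` attribute holding the closed-form area.
#' @export
roc_points <- function(model, n_points = 512L) {
  stopifnot(inherits(model, "binormal_model"))
  if (n_points < 2L) stop("n_points must be >= 2")
  lo <- min(model$mu0 - 4 * model$sigma0, model$mu1 - 4 * model$sigma1)
  hi <- max(model$mu0 + 4 * model$sigma0, model$mu1 + 4 * model$sigma1)
  x <- seq(lo, hi, length.out = n_points)
  ss <- parametric_se_sp(model, exp(x))
  out <- data.frame(
    threshold = ss$threshold,
    fpr = 1 - ss$specificity,
    tpr = ss$sensitivity
  )
  attr(out, "auc") <- binormal_auc(model)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Trapezoidal area of an evaluated ROC curve
#'
#' Numerical check on the closed-form AUC: integrates tpr over fpr with
#' the trapezoid rule, extending the curve to its (0,0) and (1,1) corners.
#'
#' @param curve A `"roc_curve"` from [roc_points()].
#' @return Trapezoidal area estimate.
#' @export
trapezoid_auc <- function(curve) {
  o <- order(curve$fpr)
  fpr <- c(0, curve$fpr[o], 1)
  tpr <- c(0, curve$tpr[o], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
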