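# Utility-based optimal threshold selection.
#
# The net utility of calling the test positive above threshold t is
#   U(t) = p * Se(t) - (1 - p) * (r / (1 - r)) * (1 - Sp(t))
# where p is the pre-test probability of the target condition and r the
# risk cut-off preference: the posterior probability of disease at which
# the clinician accepts triggering further work-up. Maximising U is
# equivalent to thresholding the posterior probability at r; at
# p = r = 0.5 it reduces to maximising the Youden index Se + Sp - 1.

#' Decision parameters: pre-test probability and risk cut-off preference
#'
#' @param p Pre-test probability (prevalence among tested patients) of the
#'   target condition, in (0, 1). Default 0.15: the observed proportion of
#'   non-length-dependent neuropathy among electrodiagnostic studies for
#'   polyneuropathy in the source department.
#' @param r Risk cut-off preference in (0, 1): the posterior probability
#'   of disease above which additional testing is triggered. Default 0.15
#'   (expert-panel choice), i.e. accepting (1 - r)/r ~ 5.7 unnecessary
#'   work-ups per avoided missed diagnosis; see
#'   [wrongly_tested_per_case()].
#' @return An object of class `"decision_params"`.
#' @export
decision_params <- function(p = 0.15, r = 0.15) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("p must be in (0, 1)")
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1)
    stop("r must be in (0, 1)")
  structure(list(p = p, r = r), class = "decision_params")
}

#' Net utility of a positivity threshold
#'
#' \deqn{U(t) = p\,Se(t) - (1-p)\frac{r}{1-r}\,(1 - Sp(t))}
#' the net-benefit form whose maximiser is the threshold at which the
#' posterior probability of disease equals `r`. `U` tends to 0 as
#' `t -> Inf` (nobody tests positive) and to `p - (1-p) r/(1-r)` as
#' `t -> 0` (everybody does); a perfect test attains `U = p`.
#'
#' @param threshold Positive threshold(s); vectorized.
#' @param model A `"binormal_model"`.
#' @param params A [decision_params()] object.
#' @return Net utility value(s).
#' @export
net_utility <- function(threshold, model, params) {
  stopifnot(inherits(params, "decision_params"))
  ss <- parametric_se_sp(model, threshold)
  w <- params$r / (1 - params$r)
  params$p * ss$sensitivity - (1 - params$p) * w * (1 - ss$specificity)
}

# Likelihood-ratio constant at which U'(log t) = 0:
# f1(x)/f0(x) = k  with  k = (r/(1-r)) * ((1-p)/p)
lr_constant <- function(params) {
  (params$r / (1 - params$r)) * ((1 - params$p) / params$p)
}

# Roots (on the log-threshold scale) of f1(x)/f0(x) = k for two Gaussian
# densities; quadratic when sigma0 != sigma1, linear when equal.
lr_equation_roots <- function(model, k) {
  m0 <- model$mu0; s0 <- model$sigma0
  m1 <- model$mu1; s1 <- model$sigma1
  A <- 1 / (2 * s0^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m0 / s0^2
  C <- m0^2 / (2 * s0^2) - m1^2 / (2 * s1^2) + log(s0 / s1) - log(k)
  if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
}

# Brute-force fallback: log-spaced grid over the data envelope, polished
# by golden-section optimisation to ~1e-6 on log(t).
grid_search_threshold <- function(model, params, n_grid = 1e5) {
  lo <- min(model$mu0 - 4 * model$sigma0, model$mu1 - 4 * model$sigma1)
  hi <- max(model$mu0 + 4 * model$sigma0, model$mu1 + 4 * model$sigma1)
  x <- seq(lo, hi, length.out = n_grid)
  u <- net_utility(exp(x), model, params)
  i <- which.max(u)
  bracket <- c(x[max(1L, i - 1L)], x[min(n_grid, i + 1L)])
  opt <- stats::optimize(function(z) net_utility(exp(z), model, params),
                         interval = bracket, maximum = TRUE, tol = 1e-7)
  exp(opt$maximum)
}

#' Utility-optimal positivity threshold
#'
#' Solves the stationarity condition of the net utility: the threshold at
#' which the likelihood ratio of the two fitted log-scale densities equals
#' \eqn{k = \frac{r}{1-r}\cdot\frac{1-p}{p}} — a quadratic in
#' \eqn{\ln t} under unequal group variances, linear under equal
#' variances. Among real roots, the one lying inside the data envelope
#' \eqn{[\exp(\mu_0 - 4\sigma_0),\ \exp(\mu_1 + 4\sigma_1)]} with maximal
#' utility is returned (the binormal likelihood ratio is non-monotone, so
#' a second, non-physiological root exists far below any observed ratio).
#' When no admissible root exists, a log-spaced grid search with local
#' polish is used instead. At the returned threshold the posterior
#' probability of disease equals `r` ([posterior_probability()]).
#'
#' @param model A `"binormal_model"`.
#' @param params A [decision_params()] object.
#' @param round_mode Rounding rule for the practical threshold; see
#'   [round_threshold()].
#' @return An object of class `"threshold_result"`: list with
#'   `threshold_star` (exact optimum), `threshold_rounded`,
#'   `utility_at_star`, `params`, `round_mode`, and `ci_lower`/`ci_upper`
#'   (`NA` until filled by [bootstrap_ci()]).
#' @export
optimal_threshold <- function(model, params = decision_params(),
                              round_mode = "floor2") {
  stopifnot(inherits(model, "binormal_model"),
            inherits(params, "decision_params"))
  k <- lr_constant(params)
  roots <- lr_equation_roots(model, k)
  lo <- model$mu0 - 4 * model$sigma0
  hi <- model$mu1 + 4 * model$sigma1
  roots <- roots[roots >= lo & roots <= hi]
  if (length(roots)) {
    u <- net_utility(exp(roots), model, params)
    t_star <- exp(roots[which.max(u)])
    # guard against a stationary point that is not the global optimum
    # (possible for reversed-direction models): the envelope endpoints
    # must not beat the root
    if (max(net_utility(exp(c(lo, hi)), model, params)) > max(u) + 1e-12)
      t_star <- grid_search_threshold(model, params)
  } else {
    t_star <- grid_search_threshold(model, params)
  }
  structure(
    list(
      threshold_star = t_star,
      threshold_rounded = round_threshold(t_star, round_mode),
      utility_at_star = net_utility(t_star, model, params),
      params = params,
      round_mode = round_mode,
      ci_lower = NA_real_,
      ci_upper = NA_real_
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("optimal threshold: %.4f (rounded %s: %.2f)\n",
              x$threshold_star, x$round_mode, x$threshold_rounded))
  cat(sprintf("  p = %.3f, r = %.3f, utility = %.4f\n",
              x$params$p, x$params$r, x$utility_at_star))
  if (!is.na(x$ci_lower))
    cat(sprintf("  95%% bootstrap CI: %.3f-%.3f\n", x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Posterior probability of disease at a marker value
#'
#' Bayes' rule with the two fitted log-scale Gaussian densities:
#' \deqn{P(D \mid x) = \frac{p\,f_1(x)}{p\,f_1(x) + (1-p)\,f_0(x)}},
#' evaluated at \eqn{x = \ln(\mathrm{value})}. At the utility-optimal
#' threshold the posterior equals the risk cut-off preference `r`.
#'
#' @param srar_value Positive marker value(s); vectorized.
#' @param model A `"binormal_model"`.
#' @param p Pre-test probability in (0, 1).
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_probability <- function(srar_value, model, p) {
  stopifnot(inherits(model, "binormal_model"))
  if (any(srar_value <= 0)) stop("srar_value must be positive")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  x <- log(srar_value)
  f1 <- stats::dnorm(x, model$mu1, model$sigma1)
  f0 <- stats::dnorm(x, model$mu0, model$sigma0)
  p * f1 / (p * f1 + (1 - p) * f0)
}

#' Accepted unnecessary work-ups per avoided missed diagnosis
#'
#' The risk cut-off preference `r` is the posterior probability of disease
#' at which further testing becomes acceptable; equivalently the clinician
#' accepts false-positive-to-true-positive odds of `(1 - r)/r`. At
#' `r = 0.15` this is 5.67: about 5.7 patients without the condition sent
#' for additional tests per avoided missed diagnosis.
#'
#' @param r Risk cut-off preference(s) in (0, 1); vectorized.
#' @return `(1 - r)/r`, in patients per case.
#' @export
wrongly_tested_per_case <- function(r) {
  if (any(r <= 0 | r >= 1)) stop("r must be in (0, 1)")
  (1 - r) / r
}

#' Round a threshold for practical use
#'
#' `"floor2"` truncates to two decimals (e.g. 0.339 -> 0.33, the
#' rounding-for-ease-of-use convention); `"nearest2"` rounds
#' half-away-from-zero (0.339 -> 0.34).
#'
#' @param threshold Positive threshold(s); vectorized.
#' @param mode `"floor2"` or `"nearest2"`.
#' @return Rounded threshold(s).
#' @export
round_threshold <- function(threshold, mode = c("floor2", "nearest2")) {
  mode <- match.arg(mode)
  if (any(threshold <= 0)) stop("threshold must be positive")
  switch(mode,
    floor2 = floor(threshold * 100 + 1e-9) / 100,
    nearest2 = floor(threshold * 100 + 0.5) / 100
  )
}

#' Optimal-threshold sensitivity grid
#'
#' Evaluates [optimal_threshold()] over a grid of pre-test probabilities
#' and risk cut-off preferences — the sensitivity analysis showing how the
#' recommended threshold moves with the two decision parameters. Pairs
#' with equal \eqn{k = \frac{r}{1-r}\cdot\frac{1-p}{p}} (in particular all
#' `p == r` pairs) yield identical thresholds.
#'
#' @param model A `"binormal_model"`.
#' @param p_values,r_values Grid values, all in (0, 1).
#' @return An object of class `"grid_result"`: list with `p_values`,
#'   `r_values`, and `thresholds`, a `length(p_values) x length(r_values)`
#'   matrix of optimal thresholds.
#' @export
sensitivity_grid <- function(model,
                             p_values = seq(0.05, 0.5, by = 0.05),
                             r_values = seq(0.05, 0.5, by = 0.05)) {
  if (any(p_values <= 0 | p_values >= 1) || any(r_values <= 0 | r_values >= 1))
    stop("grid values must be in (0, 1)")
  th <- matrix(NA_real_, length(p_values), length(r_values),
               dimnames = list(p = format(p_values), r = format(r_values)))
  for (i in seq_along(p_values)) {
    for (j in seq_along(r_values)) {
      th[i, j] <- optimal_threshold(
        model, decision_params(p_values[i], r_values[j]))$threshold_star
    }
  }
  structure(list(p_values = p_values, r_values = r_values, thresholds = th),
            class = "grid_result")
}

#' @rdname sensitivity_grid
#' @param x A `"grid_result"`.
#' @param ... Unused.
#' @return `as.data.frame` returns the grid in long format (`p`, `r`,
#'   `threshold`), suitable for heat-map plotting.
#' @export
as.data.frame.grid_result <- function(x, ...) {
  data.frame(
    p = rep(x$p_values, times = length(x$r_values)),
    r = rep(x$r_values, each = length(x$p_values)),
    threshold = as.vector(x$thresholds)
  )
}
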