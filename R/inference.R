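# Uncertainty and downstream performance: percentile bootstrap,
# prevalence-adjusted predictive values, covariate association tests.

#' Bayes positive and negative predictive values
#'
#' Post-test probabilities at a stated pre-test probability `p`:
#' \deqn{PPV = \frac{Se\,p}{Se\,p + (1-Sp)(1-p)}, \qquad
#'       NPV = \frac{Sp\,(1-p)}{Sp\,(1-p) + (1-Se)\,p}}
#' Zero denominators are resolved by limit: a test that can never be
#' positive (`Se = 0`, `Sp = 1`) has `PPV = 1` in the limit `Se -> 0+`,
#' and symmetrically `NPV = 1` when `Se = 1`, `Sp = 0`.
#'
#' @param sensitivity,specificity Probabilities in `[0, 1]`; vectorized.
#' @param pretest Pre-test probability in `(0, 1)` (boundaries handled as
#'   limits).
#' @return A list with `ppv` and `npv`.
#'
#' @examples
#' ppv_npv(0.844, 0.869, 0.15)
#'
#' @export
ppv_npv <- function(sensitivity, specificity, pretest) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1) ||
      any(pretest < 0 | pretest > 1))
    stop("all inputs must be probabilities in [0, 1]")
  num_p <- sensitivity * pretest
  den_p <- num_p + (1 - specificity) * (1 - pretest)
  num_n <- specificity * (1 - pretest)
  den_n <- num_n + (1 - sensitivity) * pretest
  ppv <- ifelse(den_p == 0, 1, num_p / den_p)
  npv <- ifelse(den_n == 0, 1, num_n / den_n)
  list(ppv = ppv, npv = npv)
}

#' Diagnostic performance at a fixed threshold
#'
#' Sensitivity and specificity of the rule "positive when marker >
#' threshold", either model-based (`"parametric"`: normal-theory Se/Sp
#' from the fitted binormal model) or empirical (`"empirical"`: observed
#' fractions above/below the threshold per group). Predictive values are
#' added via [ppv_npv()] when a pre-test probability is supplied.
#' Subgroup performance (e.g. each positive diagnosis against the same
#' negative reference group) is obtained by refitting or refiltering the
#' positive group before calling this function.
#'
#' @param model A `"binormal_model"` (required for parametric mode).
#' @param threshold Positive threshold.
#' @param pretest Optional pre-test probability for PPV/NPV.
#' @param mode `"parametric"` or `"empirical"`.
#' @param values,labels Marker values and binary labels (empirical mode).
#' @return An object of class `"diagnostic_performance"`: list with
#'   `threshold`, `mode`, `sensitivity`, `specificity`, and `ppv`, `npv`,
#'   `pretest` when a pre-test probability was supplied.
#' @export
diagnostic_performance <- function(model = NULL, threshold,
                                   pretest = NULL,
                                   mode = c("parametric", "empirical"),
                                   values = NULL, labels = NULL) {
  mode <- match.arg(mode)
  if (threshold <= 0) stop("threshold must be positive")
  if (mode == "parametric") {
    if (is.null(model)) stop("parametric mode requires a model")
    ss <- parametric_se_sp(model, threshold)
    se <- ss$sensitivity; sp <- ss$specificity
  } else {
    if (is.null(values) || is.null(labels))
      stop("empirical mode requires values and labels")
    if (is.logical(labels)) labels <- as.integer(labels)
    keep <- !is.na(values)
    values <- values[keep]; labels <- labels[keep]
    if (!sum(labels == 1) || !sum(labels == 0))
      stop("empirical mode requires observations in both groups")
    se <- mean(values[labels == 1] > threshold)
    sp <- mean(values[labels == 0] <= threshold)
  }
  out <- list(threshold = threshold, mode = mode,
              sensitivity = se, specificity = sp)
  if (!is.null(pretest)) {
    pv <- ppv_npv(se, sp, pretest)
    out$pretest <- pretest
    out$ppv <- pv$ppv
    out$npv <- pv$npv
  }
  structure(out, class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("performance at threshold %.3g (%s)\n", x$threshold, x$mode))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  if (!is.null(x$ppv))
    cat(sprintf("  PPV %.1f%%, NPV %.1f%% at %.0f%% pre-test probability\n",
                100 * x$ppv, 100 * x$npv, 100 * x$pretest))
  invisible(x)
}

# percentile rule: nearest order statistic, ceiling convention, fixed for
# reproducibility
percentile_bounds <- function(stats_vec, level = 0.95) {
  s <- sort(stats_vec)
  B <- length(s)
  alpha <- (1 - level) / 2
  # epsilon guards against ceiling(5 + 1e-16) = 6 from floating point
  c(lower = s[max(1L, ceiling(alpha * B - 1e-9))],
    upper = s[min(B, ceiling((1 - alpha) * B - 1e-9))])
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients with replacement -- stratified within disease group
#' by default, matching a case-control design with fixed group sizes --
#' and recomputes the statistic on each replicate, refitting the binormal
#' model each time. The interval is formed from the empirical 2.5th and
#' 97.5th percentiles of the replicate distribution (nearest-order-
#' statistic ceiling rule). Replicates on which the model is degenerate
#' (e.g. zero within-group variance) are redrawn and counted.
#'
#' @param values Positive marker values.
#' @param labels Binary group labels (1 = positive group).
#' @param statistic `"auc"`, `"threshold"`, `"se"`, `"sp"`, or a function
#'   `f(values, labels)` returning a scalar. `"se"`/`"sp"` are the
#'   parametric sensitivity/specificity of the refitted model at
#'   `threshold`; `"threshold"` is the utility-optimal threshold at
#'   `params`.
#' @param n_replicates Number of bootstrap replicates (default 2000).
#' @param seed Optional integer seed for reproducibility.
#' @param stratified Resample within label groups (default `TRUE`).
#' @param threshold Fixed threshold for `"se"`/`"sp"`.
#' @param params [decision_params()] for `"threshold"`.
#' @param level Confidence level (default 0.95).
#'
#' @return An object of class `"bootstrap_ci"`: list with `point` (full-
#'   data estimate), `lower`, `upper`, `level`, `n_replicates`,
#'   `n_redrawn`, and `replicates` (the replicate statistics).
#' @export
bootstrap_ci <- function(values, labels, statistic = "auc",
                         n_replicates = 2000L, seed = NULL,
                         stratified = TRUE,
                         threshold = NULL, params = NULL,
                         level = 0.95) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (is.logical(labels)) labels <- as.integer(labels)
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  stat_fun <- if (is.function(statistic)) statistic else switch(
    match.arg(statistic, c("auc", "threshold", "se", "sp")),
    auc = function(v, l) binormal_auc(fit_binormal(v, l)),
    threshold = {
      if (is.null(params)) params <- decision_params()
      function(v, l) optimal_threshold(fit_binormal(v, l),
                                       params)$threshold_star
    },
    se = {
      if (is.null(threshold)) stop("statistic 'se' requires a threshold")
      function(v, l) parametric_se_sp(fit_binormal(v, l),
                                      threshold)$sensitivity
    },
    sp = {
      if (is.null(threshold)) stop("statistic 'sp' requires a threshold")
      function(v, l) parametric_se_sp(fit_binormal(v, l),
                                      threshold)$specificity
    }
  )
  if (!is.null(seed)) set.seed(seed)
  point <- stat_fun(values, labels)
  i0 <- which(labels == 0)
  i1 <- which(labels == 1)
  n <- length(values)
  reps <- numeric(n_replicates)
  n_redrawn <- 0L
  for (b in seq_len(n_replicates)) {
    repeat {
      idx <- if (stratified)
        c(sample(i0, length(i0), replace = TRUE),
          sample(i1, length(i1), replace = TRUE))
      else
        sample.int(n, n, replace = TRUE)
      val <- tryCatch(stat_fun(values[idx], labels[idx]),
                      error = function(e) NULL)
      if (!is.null(val) && is.finite(val)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_replicates)
        stop("bootstrap failed: too many degenerate replicates")
    }
    reps[b] <- val
  }
  bounds <- percentile_bounds(reps, level)
  structure(
    list(point = point, lower = bounds[["lower"]],
         upper = bounds[["upper"]], level = level,
         n_replicates = n_replicates, n_redrawn = n_redrawn,
         replicates = reps),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("point %.4f, %.0f%% percentile CI %.4f-%.4f (B = %d",
              x$point, 100 * x$level, x$lower, x$upper, x$n_replicates))
  if (x$n_redrawn > 0) cat(sprintf(", %d redrawn", x$n_redrawn))
  cat(")\n")
  invisible(x)
}

#' Covariate association screen for the marker
#'
#' The pre-specified association tests for a diagnostic-marker cohort:
#' Pearson correlation of the marker with age (with Fisher-z 95% CI and
#' two-sided p), a Wilcoxon rank-sum test across sex (normal
#' approximation with tie correction), and a Kruskal-Wallis test across
#' etiology classes within the group named by `etiology_group`. All tests
#' are two-sided and unadjusted (three pre-specified comparisons). A
#' covariate with fewer than two observed levels is skipped with a
#' warning.
#'
#' @param srar_tab Per-patient table from [srar_table()] (needs `srar`,
#'   `calculable`, `age`, `sex`, `etiology_class`, `group`).
#' @param etiology_group Group within which the etiology test runs
#'   (default `"SNN"`).
#' @return A list with components `age` (estimate, CI, p), `sex`
#'   (W statistic, p) and `etiology` (chi-squared statistic, df, p);
#'   skipped tests are `NULL`.
#' @export
covariate_associations <- function(srar_tab, etiology_group = "SNN") {
  d <- srar_tab[srar_tab$calculable & !is.na(srar_tab$srar), , drop = FALSE]
  if (!nrow(d)) stop("no calculable marker values")
  out <- list(age = NULL, sex = NULL, etiology = NULL)
  if ("age" %in% names(d) && stats::sd(d$age) > 0) {
    ct <- stats::cor.test(d$age, d$srar, method = "pearson")
    out$age <- list(estimate = unname(ct$estimate),
                    ci = as.numeric(ct$conf.int),
                    p_value = ct$p.value)
  } else warning("age test skipped (constant or missing)")
  if ("sex" %in% names(d) && length(unique(d$sex)) == 2L) {
    wt <- stats::wilcox.test(srar ~ sex, data = d,
                             exact = FALSE, correct = TRUE)
    out$sex <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
  } else warning("sex test skipped (fewer than two levels)")
  e <- d[d$group == etiology_group, , drop = FALSE]
  if (nrow(e) && "etiology_class" %in% names(e) &&
      length(unique(e$etiology_class)) >= 2L) {
    kt <- stats::kruskal.test(e$srar, factor(e$etiology_class))
    out$etiology <- list(statistic = unname(kt$statistic),
                         df = unname(kt$parameter),
                         p_value = kt$p.value)
  } else warning("etiology test skipped (fewer than two classes)")
  out
}
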