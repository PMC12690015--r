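test_that("Bayes predictive values have their analytic special cases", {
  pv <- ppv_npv(1, 1, 0.3)
  expect_equal(pv$ppv, 1)
  expect_equal(pv$npv, 1)
  # an uninformative test returns the prior
  for (p in c(0.1, 0.15, 0.5, 0.9)) {
    pv <- ppv_npv(0.5, 0.5, p)
    expect_equal(pv$ppv, p)
    expect_equal(pv$npv, 1 - p)
  }
  # zero-denominator limits
  expect_equal(ppv_npv(0, 1, 0.15)$ppv, 1)
  expect_equal(ppv_npv(1, 0, 0.15)$npv, 1)
  expect_error(ppv_npv(1.2, 0.5, 0.5), "probabilities")
})

test_that("predictive values are monotone in the pre-test probability", {
  set.seed(97)
  for (i in 1:20) {
    se <- runif(1, 0.55, 0.99)
    sp <- runif(1, 0.55, 0.99)  # informative test: Se + Sp > 1
    p <- sort(runif(5, 0.01, 0.99))
    pv <- ppv_npv(se, sp, p)
    expect_true(all(diff(pv$ppv) > 0))
    expect_true(all(diff(pv$npv) < 0))
  }
})

test_that("diagnostic performance composes the model and Bayes' rule", {
  m <- published_model()
  perf <- diagnostic_performance(m, exp(m$mu1), pretest = 0.15)
  expect_equal(perf$sensitivity, 0.5)
  # internal consistency: PPV/NPV equal ppv_npv of the reported Se/Sp
  pv <- ppv_npv(perf$sensitivity, perf$specificity, 0.15)
  expect_identical(perf$ppv, pv$ppv)
  expect_identical(perf$npv, pv$npv)

  # empirical mode with perfect separation
  v <- c(0.1, 0.12, 0.15, 0.6, 0.8, 1.2)
  l <- c(0, 0, 0, 1, 1, 1)
  perf <- diagnostic_performance(threshold = 0.33, mode = "empirical",
                                 values = v, labels = l)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  # empirical counts at a non-separating threshold
  perf <- diagnostic_performance(threshold = 0.7, mode = "empirical",
                                 values = v, labels = l)
  expect_equal(perf$sensitivity, 2 / 3)
  expect_equal(perf$specificity, 1)
  expect_error(diagnostic_performance(threshold = 0.33, mode = "empirical",
                                      values = v, labels = rep(1, 6)),
               "both groups")
})

test_that("the percentile bootstrap is reproducible and order-statistic based", {
  set.seed(103)
  m <- published_model()
  v <- c(rlnorm(30, m$mu0, m$sigma0), rlnorm(60, m$mu1, m$sigma1))
  l <- rep(c(0, 1), c(30, 60))
  ci1 <- bootstrap_ci(v, l, "auc", n_replicates = 200, seed = 5)
  ci2 <- bootstrap_ci(v, l, "auc", n_replicates = 200, seed = 5)
  expect_identical(ci1[c("point", "lower", "upper")],
                   ci2[c("point", "lower", "upper")])
  expect_equal(ci1$point, binormal_auc(fit_binormal(v, l)))
  # interval endpoints are order statistics of the replicate values
  expect_true(ci1$lower %in% ci1$replicates)
  expect_true(ci1$upper %in% ci1$replicates)
  expect_identical(ci1$lower, sort(ci1$replicates)[5L])
  expect_identical(ci1$upper, sort(ci1$replicates)[195L])
  expect_lte(ci1$lower, ci1$point)
  expect_gte(ci1$upper, ci1$point)
  # default replicate count follows the published analysis plan
  expect_identical(eval(formals(bootstrap_ci)$n_replicates), 2000L)

  # degenerate statistic on constant data collapses to the point
  ci <- bootstrap_ci(rep(2, 40), rep(c(0, 1), 20),
                     statistic = function(v, l) mean(v),
                     n_replicates = 100, seed = 1)
  expect_identical(ci$lower, 2)
  expect_identical(ci$upper, 2)
  expect_identical(ci$point, 2)
})

test_that("the percentile interval tracks the t-interval for a normal mean", {
  set.seed(107)
  x <- rnorm(200, mean = 3, sd = 2)
  ci <- bootstrap_ci(x, rep(c(0, 1), 100),
                     statistic = function(v, l) mean(v),
                     n_replicates = 2000, seed = 11, stratified = FALSE)
  t_half <- qt(0.975, 199) * sd(x) / sqrt(200)
  boot_half <- (ci$upper - ci$lower) / 2
  expect_lt(abs(boot_half - t_half) / t_half, 0.10)
  expect_lt(abs((ci$upper + ci$lower) / 2 - mean(x)), 0.1 * t_half + 0.05)
})

test_that("bootstrap thresholds bracket the full-data optimum", {
  set.seed(109)
  m <- published_model()
  v <- c(rlnorm(30, m$mu0, m$sigma0), rlnorm(60, m$mu1, m$sigma1))
  l <- rep(c(0, 1), c(30, 60))
  ci <- bootstrap_ci(v, l, "threshold", n_replicates = 200, seed = 7,
                     params = decision_params(0.15, 0.15))
  expect_equal(ci$point,
               optimal_threshold(fit_binormal(v, l),
                                 decision_params(0.15, 0.15))$threshold_star)
  expect_lt(ci$lower, ci$point)
  expect_gt(ci$upper, ci$point)
  # se/sp statistics demand a threshold
  expect_error(bootstrap_ci(v, l, "se", n_replicates = 10), "threshold")
  ci_se <- bootstrap_ci(v, l, "se", threshold = 0.33,
                        n_replicates = 100, seed = 3)
  expect_true(ci_se$lower >= 0 && ci_se$upper <= 1)
})

test_that("covariate association tests match their reference behaviour", {
  # marker exactly linear in age: correlation one
  tab <- data.frame(
    patient_id = sprintf("P%02d", 1:20), group = "SNN",
    age = 21:40, sex = rep(c("male", "female"), 10),
    etiology_class = rep(c("immune-mediated", "inherited", "other"),
                         length.out = 20),
    srar = (21:40) / 50, calculable = TRUE
  )
  a <- covariate_associations(tab)
  expect_equal(a$age$estimate, 1)

  # identical marker multisets in both sexes: rank-sum at its null mean
  tab2 <- tab
  tab2$srar <- rep(c(0.3, 0.5, 0.7, 0.9), 5)
  tab2$sex <- rep(c("male", "female"), each = 10)
  tab2$srar[tab2$sex == "female"] <- tab2$srar[tab2$sex == "male"]
  a2 <- covariate_associations(tab2)
  expect_equal(a2$sex$statistic, 10 * 10 / 2)

  # single-level covariates are skipped with a warning
  tab3 <- tab
  tab3$sex <- "male"
  expect_warning(a3 <- covariate_associations(tab3), "sex")
  expect_null(a3$sex)
})

test_that("the Kruskal-Wallis approximation agrees with exact enumeration", {
  # three groups of four, distinct values: enumerate all 34650 partitions
  vals <- c(2.7, 3.7, 5.7, 9.1, 2.0, 9.0, 9.4, 6.6, 6.3, 0.6, 2.1, 1.8)
  grp <- rep(c("a", "b", "c"), each = 4)
  kw_p <- kruskal.test(vals, factor(grp))$p.value

  r <- rank(vals)
  N <- 12L
  h_stat <- function(i1, i2) {
    R1 <- sum(r[i1]); R2 <- sum(r[i2]); R3 <- sum(r) - R1 - R2
    12 / (N * (N + 1)) * (R1^2 + R2^2 + R3^2) / 4 - 3 * (N + 1)
  }
  h_obs <- h_stat(1:4, 5:8)
  idx <- seq_len(N)
  count <- 0L; total <- 0L
  c1 <- utils::combn(idx, 4)
  for (j in seq_len(ncol(c1))) {
    rest <- setdiff(idx, c1[, j])
    c2 <- utils::combn(rest, 4)
    for (k in seq_len(ncol(c2))) {
      total <- total + 1L
      if (h_stat(c1[, j], c2[, k]) >= h_obs - 1e-12) count <- count + 1L
    }
  }
  p_exact <- count / total
  expect_lt(abs(kw_p - p_exact), 0.02)

  # the same data through the package surface
  tab <- data.frame(
    patient_id = sprintf("P%02d", 1:12), group = "SNN",
    age = rnorm(12, 60, 5), sex = rep(c("male", "female"), 6),
    etiology_class = grp, srar = vals, calculable = TRUE
  )
  a <- covariate_associations(tab)
  expect_equal(a$etiology$p_value, kw_p)
})
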