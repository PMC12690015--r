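# shared fixtures: calibrated models, random models, hand-built records

# log-normal parameters moment-matched to the published group summaries:
# NLDN median 0.74 (IQR 0.50-1.00), LDN median 0.17 (IQR 0.12-0.23)
published_nldn <- function() calibrate_lognormal(0.74, 0.50, 1.00)
published_ldn <- function() calibrate_lognormal(0.17, 0.12, 0.23)

published_model <- function(n0 = 30L, n1 = 60L) {
  p1 <- published_nldn()
  p0 <- published_ldn()
  binormal_model(p0$mu, p0$sigma, p1$mu, p1$sigma, n0 = n0, n1 = n1)
}

# random binormal model with moderate separation; positive group higher
random_model <- function() {
  mu0 <- stats::runif(1, -2.5, -0.5)
  binormal_model(
    mu0 = mu0, sigma0 = stats::runif(1, 0.3, 1.2),
    mu1 = mu0 + stats::runif(1, 0.5, 2.5), sigma1 = stats::runif(1, 0.3, 1.2)
  )
}

# measurement data frame for one patient; NA = absent response
measurements <- function(sural_left = NA, sural_right = NA,
                         radial_left = NA, radial_right = NA,
                         study_index = 1L) {
  data.frame(
    nerve = c("sural", "sural", "radial", "radial"),
    side = c("left", "right", "left", "right"),
    amplitude_uV = c(sural_left, sural_right, radial_left, radial_right),
    study_index = study_index,
    stringsAsFactors = FALSE
  )
}

# long-format cohort from per-patient single-side amplitudes
cohort_from_amplitudes <- function(group, sural, radial) {
  n <- length(group)
  data.frame(
    patient_id = rep(sprintf("P%04d", seq_len(n)), each = 2L),
    group = rep(group, each = 2L),
    age = 60,
    sex = rep(rep(c("male", "female"), length.out = n), each = 2L),
    etiology_class = "other",
    nerve = rep(c("sural", "radial"), n),
    side = "left",
    amplitude_uV = as.vector(rbind(sural, radial)),
    study_index = 1L,
    stringsAsFactors = FALSE
  )
}

# independent brute-force maximiser of the net utility, written from the
# Se/Sp closed forms directly (does not call the package's solver)
oracle_threshold <- function(model, p, r, n_grid = 2e4) {
  x <- seq(min(model$mu0 - 4 * model$sigma0, model$mu1 - 4 * model$sigma1),
           max(model$mu0 + 4 * model$sigma0, model$mu1 + 4 * model$sigma1),
           length.out = n_grid)
  u_of <- function(z) {
    se <- pnorm((model$mu1 - z) / model$sigma1)
    sp <- pnorm((z - model$mu0) / model$sigma0)
    p * se - (1 - p) * (r / (1 - r)) * (1 - sp)
  }
  i <- which.max(u_of(x))
  opt <- stats::optimize(u_of, c(x[max(1, i - 1)], x[min(n_grid, i + 1)]),
                         maximum = TRUE, tol = 1e-9)
  exp(opt$maximum)
}
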