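# Patient-level rules: amplitude selection, SRAR, length-dependent
# pattern, low-amplitude flags, and cohort summaries.

#' Select the SNAP amplitude used for the ratio
#'
#' Applies the measurement-selection rules: only the first study
#' (`study_index == 1`) contributes, and when both sides were assessed the
#' lower recordable amplitude is used. An absent response on one side does
#' not count as zero: the recordable side is used.
#'
#' @param measurements Data frame of one patient's measurements with
#'   columns `nerve`, `side`, `amplitude_uV` (`NA` = absent) and
#'   optionally `study_index` (assumed 1 when missing).
#' @param nerve Which nerve to select, `"sural"` or `"radial"`.
#'
#' @return The selected amplitude in microvolts, or `NA_real_` if no side
#'   has a recordable response.
#' @export
select_amplitude <- function(measurements, nerve = c("sural", "radial")) {
  nerve <- match.arg(nerve)
  if (!is.data.frame(measurements) ||
      !all(c("nerve", "amplitude_uV") %in% names(measurements)))
    stop("measurements must have columns 'nerve' and 'amplitude_uV'")
  amp <- measurements$amplitude_uV
  if (any(!is.na(amp) & amp < 0))
    stop("negative SNAP amplitude in measurements")
  idx <- if ("study_index" %in% names(measurements))
    measurements$study_index == 1L else TRUE
  amp <- amp[idx & measurements$nerve == nerve]
  amp <- amp[!is.na(amp)]
  if (!length(amp)) NA_real_ else min(amp)
}

#' Compute the sural/radial amplitude ratio for one patient
#'
#' SRAR = selected sural amplitude / selected radial amplitude, after the
#' lower-of-sides and first-study rules. The ratio is calculable only when
#' both nerves have a recordable response and the radial amplitude is
#' positive; a zero radial amplitude yields a non-calculable result rather
#' than an infinite ratio. The ratio is invariant under rescaling all
#' amplitudes by a common positive factor.
#'
#' @param measurements Data frame of one patient's measurements (see
#'   [select_amplitude()]).
#'
#' @return A list with `srar` (ratio, or `NA` when non-calculable),
#'   `sural_used`, `radial_used` (microvolts, `NA` when absent) and
#'   `calculable` (logical).
#' @export
compute_srar <- function(measurements) {
  sural <- select_amplitude(measurements, "sural")
  radial <- select_amplitude(measurements, "radial")
  calculable <- !is.na(sural) && !is.na(radial) && radial > 0
  list(
    srar = if (calculable) sural / radial else NA_real_,
    sural_used = sural,
    radial_used = radial,
    calculable = calculable
  )
}

#' Classify the length-dependent electrodiagnostic pattern
#'
#' The length-dependent pattern is a sural SNAP amplitude strictly lower
#' than the radial SNAP amplitude, irrespective of their ratio. A tie is
#' not a pattern ("lower than" is strict). When either selected amplitude
#' is absent the pattern is indeterminate (`NA`). Whenever the SRAR is
#' calculable, pattern presence is equivalent to SRAR < 1.
#'
#' @inheritParams compute_srar
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate).
#' @export
classify_ld_pattern <- function(measurements) {
  sural <- select_amplitude(measurements, "sural")
  radial <- select_amplitude(measurements, "radial")
  if (is.na(sural) || is.na(radial)) return(NA)
  sural < radial
}

#' Flag an abnormally low SNAP amplitude
#'
#' An amplitude is flagged low when it is below the laboratory's lower
#' limit of normal or when the response is absent altogether (an absent
#' response is abnormal). The default limits used elsewhere in the package
#' (sural 6, radial 15 microvolts) are illustrative placeholders, not
#' authoritative laboratory references.
#'
#' @param amplitude Amplitude(s) in microvolts; `NA` = absent. Vectorized.
#' @param lln Lower limit of normal in microvolts, `> 0`.
#' @return Logical vector.
#' @export
flag_low_amplitude <- function(amplitude, lln) {
  if (!is.numeric(lln) || length(lln) != 1L || lln <= 0)
    stop("lln must be a single positive number")
  is.na(amplitude) | amplitude < lln
}

#' Per-patient SRAR table from a long cohort
#'
#' Applies [compute_srar()], [classify_ld_pattern()] and
#' [flag_low_amplitude()] to every patient of a long-format cohort.
#'
#' @param cohort Long cohort data frame as produced by [simulate_cohort()]
#'   or [read_cohort()].
#' @param lln_sural,lln_radial Lower limits of normal in microvolts
#'   (defaults 6 and 15; placeholders, see [flag_low_amplitude()]).
#'
#' @return Data frame with one row per patient: `patient_id`, `group`,
#'   `age`, `sex`, `etiology_class` (when present in the input),
#'   `sural_used`, `radial_used`, `srar`, `calculable`, `ld_pattern`,
#'   `low_sural`, `low_radial`.
#' @export
srar_table <- function(cohort, lln_sural = 6, lln_radial = 15) {
  if (!nrow(cohort)) stop("empty cohort")
  ids <- unique(cohort$patient_id)
  covars <- intersect(c("group", "age", "sex", "etiology_class"),
                      names(cohort))
  first_row <- cohort[!duplicated(cohort$patient_id), c("patient_id", covars),
                      drop = FALSE]
  rownames(first_row) <- first_row$patient_id
  res <- lapply(split(cohort, factor(cohort$patient_id, levels = ids)),
                function(m) {
    s <- compute_srar(m)
    data.frame(
      sural_used = s$sural_used,
      radial_used = s$radial_used,
      srar = s$srar,
      calculable = s$calculable,
      ld_pattern = classify_ld_pattern(m),
      stringsAsFactors = FALSE
    )
  })
  out <- cbind(first_row[ids, , drop = FALSE], do.call(rbind, res))
  out$low_sural <- flag_low_amplitude(out$sural_used, lln_sural)
  out$low_radial <- flag_low_amplitude(out$radial_used, lln_radial)
  rownames(out) <- NULL
  out
}

median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Group-wise electrodiagnostic summary
#'
#' Per disease group, and for the pooled non-length-dependent group
#' (union of the groups named in `pooled`), computes the median and IQR of
#' the selected sural amplitude, radial amplitude and SRAR (calculable
#' patients only), and the counts and percentages of low sural amplitude,
#' low radial amplitude and the length-dependent pattern — the layout of a
#' standard electrodiagnostic characteristics table. When `threshold` is
#' given, a cross-tabulation of pattern presence against SRAR > threshold
#' is returned for the pooled group.
#'
#' @param srar_tab Per-patient table from [srar_table()].
#' @param pooled Character vector of group labels pooled as the
#'   non-length-dependent ("NLDN") stratum; set `NULL` to skip pooling.
#' @param threshold Optional SRAR threshold for the cross-tabulation.
#'
#' @return A list with `summary` (one row per group plus the pooled
#'   stratum) and, when `threshold` is given, `crosstab` (a 2x2 table of
#'   `ld_pattern` by `srar > threshold` among pooled patients with
#'   calculable SRAR).
#' @export
cohort_summary <- function(srar_tab, pooled = c("SNN", "CIDP"),
                           threshold = NULL) {
  if (!nrow(srar_tab)) stop("empty cohort")
  groups <- if (is.factor(srar_tab$group)) levels(srar_tab$group)
            else unique(srar_tab$group)
  strata <- stats::setNames(lapply(groups, function(g)
    srar_tab[srar_tab$group == g, , drop = FALSE]), groups)
  if (!is.null(pooled) && any(pooled %in% groups)) {
    strata$NLDN <- srar_tab[srar_tab$group %in% pooled, , drop = FALSE]
  }
  keep <- vapply(strata, nrow, integer(1)) > 0
  if (any(!keep))
    warning("omitting empty group(s): ",
            paste(names(strata)[!keep], collapse = ", "))
  strata <- strata[keep]
  rows <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    calc <- d[d$calculable, , drop = FALSE]
    su <- median_iqr(d$sural_used)
    ra <- median_iqr(d$radial_used)
    sr <- median_iqr(calc$srar)
    pat <- d$ld_pattern
    data.frame(
      stratum = nm,
      n = nrow(d),
      n_calculable = sum(d$calculable),
      sural_median = su[["median"]], sural_q1 = su[["q1"]],
      sural_q3 = su[["q3"]],
      radial_median = ra[["median"]], radial_q1 = ra[["q1"]],
      radial_q3 = ra[["q3"]],
      srar_median = sr[["median"]], srar_q1 = sr[["q1"]],
      srar_q3 = sr[["q3"]],
      low_sural_n = sum(d$low_sural, na.rm = TRUE),
      low_sural_pct = 100 * mean(d$low_sural, na.rm = TRUE),
      low_radial_n = sum(d$low_radial, na.rm = TRUE),
      low_radial_pct = 100 * mean(d$low_radial, na.rm = TRUE),
      ld_pattern_n = sum(pat, na.rm = TRUE),
      ld_pattern_pct = 100 * mean(pat, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- list(summary = do.call(rbind, rows))
  if (!is.null(threshold)) {
    pool <- strata$NLDN
    if (!is.null(pool)) {
      calc <- pool[pool$calculable & !is.na(pool$ld_pattern), , drop = FALSE]
      out$crosstab <- table(
        ld_pattern = calc$ld_pattern,
        above_threshold = calc$srar > threshold
      )
    }
  }
  out
}
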