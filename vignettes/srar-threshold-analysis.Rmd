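---
title: "Decision-theoretic SRAR thresholds: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-theoretic SRAR thresholds: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sraroc)
```

## The problem

In the electrodiagnostic work-up of polyneuropathy, distinguishing
*non-length-dependent* neuropathies (NLDN: sensory neuronopathy, SNN, and
chronic inflammatory demyelinating polyradiculoneuropathy, CIDP) from the
far more common *length-dependent* neuropathies (LDN) changes the
etiologic search and the treatment. Length-dependent ("dying-back")
axonal loss hits the longest sensory nerves first, so the sural SNAP
amplitude falls before the radial; in NLDN the radial amplitude is often
reduced as early and as severely as the sural. The **sural/radial
amplitude ratio (SRAR)** — sural SNAP amplitude divided by radial SNAP
amplitude — condenses this into one number: low in LDN, preserved or high
in NLDN.

`sraroc` implements the full evaluation pipeline for this marker:
patient-level SRAR computation, a parametric binormal ROC model,
decision-theoretic threshold selection, percentile-bootstrap uncertainty,
and prevalence-adjusted predictive values, together with a calibrated
synthetic cohort generator so the whole pipeline is testable without
patient data.

## Patient-level rules

A patient's SRAR uses, per nerve, only the **first** electrodiagnostic
study and, when both sides were assessed, the **lower** recordable
amplitude. An absent response on one side does not count as zero — the
recordable side is used — but a patient with absent responses on *both*
sides of either nerve has a non-calculable SRAR (in practice roughly 45%
of screened patients). A zero radial amplitude is treated as
non-calculable rather than as an infinite ratio. The *length-dependent
EDX pattern* is the cruder companion sign: sural amplitude strictly lower
than radial, irrespective of the ratio; a tie is not a pattern, and
whenever the SRAR is calculable the pattern is equivalent to SRAR < 1.
Low-amplitude flags compare against laboratory lower limits of normal;
the defaults (sural 6 µV, radial 15 µV) are documentation-only
placeholders, since reference limits are laboratory-specific.

## The binormal ROC model

SRAR is a positive ratio and right-skewed, so the model works on the log
scale: within each group the log-SRAR is Gaussian,

$$\ln X_0 \sim N(\mu_0, \sigma_0^2) \quad\text{(LDN)}, \qquad
  \ln X_1 \sim N(\mu_1, \sigma_1^2) \quad\text{(NLDN)}.$$

Fitting is normal-theory: per-group sample mean and SD (with the $n-1$
denominator) of the log values — deterministic, and the convention used
by standard binormal ROC software. With the positivity rule
"SRAR > t ⇒ NLDN",

$$Se(t) = \Phi\!\left(\frac{\mu_1 - \ln t}{\sigma_1}\right), \qquad
  Sp(t) = \Phi\!\left(\frac{\ln t - \mu_0}{\sigma_0}\right), \qquad
  AUC = \Phi\!\left(\frac{\mu_1 - \mu_0}{\sqrt{\sigma_0^2 +
  \sigma_1^2}}\right).$$

The direction is fixed (higher SRAR ⇒ NLDN); there is no automatic
direction detection, and zero-variance groups are rejected rather than
regularized. Subgroup curves (SNN vs LDN, CIDP vs LDN) are produced by
refitting the positive group; LDN is always the reference.

## Threshold selection as a decision problem

Two parameters describe the clinical context:

* **pre-test probability** $p$ — the prevalence of NLDN among patients
  reaching the test (default 0.15, the observed proportion in the source
  department);
* **risk cut-off preference** $r$ — the posterior probability of disease
  at which the clinician accepts triggering additional work-up (default
  0.15, an expert-panel choice). Equivalently the clinician accepts
  $(1-r)/r$ unnecessary work-ups per avoided missed diagnosis; at
  $r = 0.15$ that is $0.85/0.15 = 5.67 \approx 5.7$ patients.

The package scores a threshold by the net utility

$$U(t) = p\,Se(t) \;-\; (1-p)\,\frac{r}{1-r}\,\bigl(1 - Sp(t)\bigr).$$

This net-benefit form is the one pinned down (up to positive affine
transformation) by two published equivalences: at $p = r = 0.5$ its
maximizer is the Youden-index maximizer, and its trade-off interpretation
is exactly the $(1-r)/r$ odds above. Setting $U'(\ln t) = 0$ gives the
stationarity condition

$$\frac{f_1(\ln t)}{f_0(\ln t)} = k
  = \frac{r}{1-r}\cdot\frac{1-p}{p},$$

a quadratic in $\ln t$ when $\sigma_0 \ne \sigma_1$ (linear when equal).
Only pairs with equal $k$ matter: all $p = r$ settings give the same
threshold. At the optimum the posterior probability of disease,
$p f_1 / (p f_1 + (1-p) f_0)$, equals $r$ — the threshold is precisely
the marker value at which the post-test risk crosses the clinician's
action threshold.

**Root selection.** The binormal likelihood ratio is non-monotone under
unequal variances, so the quadratic has two roots; the package keeps the
root inside the 4-SD data envelope
$[\exp(\mu_0 - 4\sigma_0),\, \exp(\mu_1 + 4\sigma_1)]$ with maximal
utility. For the calibrated study model the discarded root sits near
$3 \times 10^{-11}$, eleven orders of magnitude below any physiologic
SRAR. When no admissible root exists (extreme $k$), the utility maximum
lies on the envelope boundary and a log-spaced grid search
($10^5$ points) with local polish (tolerance $10^{-6}$ on $\ln t$) is
used; in those boundary cases the posterior-equals-$r$ identity cannot
hold, which the tests acknowledge by asserting it only for interior
optima. The grid search doubles as an internal cross-check: root and grid
agree to $10^{-4}$ relative on random models.

**Rounding.** For bedside use the optimal threshold is rounded; the
default mode `"floor2"` truncates to two decimals (0.339 → 0.33,
one-third), matching the convention of reporting a simple fraction;
`"nearest2"` is available and the mode is carried in the result.

## Uncertainty and downstream performance

Confidence intervals use the **percentile bootstrap** with 2000
replicates by default. Resampling is stratified within disease group —
the design is case–control with fixed group sizes, so unstratified
resampling would mix in group-size variability that the design excludes —
and the binormal model is refitted on every replicate (the parametric
curve is the object of inference). Interval endpoints are the nearest
order statistics at 2.5%/97.5% (ceiling rule, with a floating-point
guard), fixed for reproducibility. Replicates with a degenerate model are
redrawn and counted.

Predictive values follow Bayes' rule at a stated pre-test probability.
Zero denominators are resolved by limits (PPV = 1 for a test that can
never be positive, symmetrically for NPV). Both parametric (model-based)
and empirical (counting) sensitivity/specificity are provided, since
published tables rarely state which was used.

The pre-specified covariate screen — Pearson correlation with age
(Fisher-z CI), Wilcoxon rank-sum across sex (normal approximation with
tie correction), Kruskal–Wallis across etiology classes within SNN — is
wired to the base R tests; all two-sided, unadjusted (three pre-specified
comparisons).

## The synthetic cohort generator

The generator works backwards from the quantity the analysis consumes.
Published cohort tables report the SRAR per group as median (IQR); a
log-normal is moment-matched by

$$\mu = \ln(\mathrm{median}), \qquad
  \sigma = \frac{\ln(Q3/Q1)}{2\,z_{0.75}}.$$

This reproduces the median and the quartile *ratio* exactly. It cannot
reproduce asymmetric quartiles individually — a log-normal's quartiles
are log-symmetric ($Q1 \cdot Q3 = \mathrm{median}^2$), and printed
targets such as 0.74 (0.50–1.00) are only approximately so. We accept
this: the median and spread are what drive the downstream threshold, and
the calibration tests assert exactly what the construction guarantees.

Per patient, one SRAR is drawn from the calibrated log-normal; left and
right radial amplitudes come from a per-group radial log-normal
(calibrated the same way to the published per-group radial medians/IQRs);
each side's sural amplitude is ratio × radial with independent
multiplicative log-normal jitter per side (default $\sigma = 0.05$), so
left and right disagree and the lower-of-sides rule is exercised
non-trivially. With zero jitter, `min(sural)/min(radial)` equals the
drawn ratio exactly — used for exact calibration tests. Non-calculability
is missing-completely-at-random at the patient-nerve level (both sides of
one randomly chosen nerve absent), with per-group default rates matching
the published screening yield (SNN 30/59 calculable, CIDP 30/43, LDN
30/62); whether absences cluster by nerve is not published, so MCAR is
the neutral choice. Age (normal, truncated at 18 — an adult cohort) and
sex are drawn independently of the SRAR, consistent with the published
null associations. A single integer seed drives every stream; identical
config and seed give bit-identical cohorts.

What the generator does *not* emulate: motor conduction and demyelinating
features, per-etiology SRAR effects (none were found), measurement
digitization, and any real dependence between missingness and disease
severity. Tests that pass on these cohorts therefore validate the
*statistical machinery* under the published summary structure, not the
clinical performance of the marker on new patients.

## Problem sizes and numerical choices

The test suite uses cohort sizes matching the study design (60 positives,
30 negatives) for end-to-end checks, 5 000–50 000 draws for convergence
and parameter-recovery checks, $10^6$-draw Monte-Carlo oracles for the
closed-form AUC and Se/Sp, 100–200 simulation seeds for threshold and
calibration summaries, and 200 cohorts × 500 bootstrap replicates for the
coverage study; the bootstrap default in analysis use remains 2000
replicates. Tolerances follow the quantity: $10^{-9}$ for algebraic
identities, $10^{-4}$ relative for root-vs-grid agreement, $10^{-6}$ for
the posterior identity, 3 Monte-Carlo standard errors for simulation
oracles.

## A worked example

```{r example}
cfg <- cohort_config(seed = 42)
tab <- srar_table(simulate_cohort(cfg))
calc <- tab[tab$calculable, ]
model <- fit_binormal(calc$srar, calc$group %in% c("SNN", "CIDP"))
model
th <- optimal_threshold(model, decision_params(p = 0.15, r = 0.15))
th
diagnostic_performance(model, th$threshold_rounded, pretest = 0.15)
```

## Known limitations

* The binormal model is an approximation; no goodness-of-fit machinery is
  provided, and heavy-tailed log-SRAR would bias the parametric Se/Sp.
* Threshold selection on the empirical (non-parametric) ROC is out of
  scope, as are covariate-adjusted ROC, partial AUC, BCa/studentized
  bootstrap and DeLong variance.
* The utility form is fixed by the two equivalences above; any
  alternative utility satisfying both would select the same threshold
  family but could differ elsewhere.
* Published point values fitted on the original patient data (AUC 0.94,
  Se 84.4%, Sp 86.9%) are not reproducible from printed summaries alone;
  the moment-matched model is sharper (AUC ≈ 0.98). The package
  reproduces the *procedure* and the CI-bounded threshold, not those
  data-fitted values.
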