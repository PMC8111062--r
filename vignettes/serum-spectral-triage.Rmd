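---
title: "Methods: simulating and evaluating a consensus-vote spectroscopic liquid biopsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating a consensus-vote spectroscopic liquid biopsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectriage)
```

## The setting

Serum ATR-FTIR liquid biopsies for brain-tumour triage work by drying a few
microlitres of serum on an optical slide, recording infrared absorbance
spectra, and classifying each spectrum with a machine-learning model. The
replicate design is three sample wells per patient with three spectrometer
scans per well, giving nine spectra per patient. The nine per-spectrum
predictions are combined by a consensus vote: the patient is reported as
"cancer" when five or more spectra vote "cancer". Performance is reported per
patient — sensitivity, specificity, predictive values and accuracy with
binomial confidence intervals — and predictive values are transported to the
much lower tumour prevalence (1–3%) of the symptomatic primary-care
population the test is meant to triage.

`spectriage` implements this whole chain as testable code: a seeded
generator of synthetic spectral cohorts, a chemometric preprocessing
pipeline, patient-grouped cross-validated classifiers, the consensus rule
with ROC threshold sweeping, and the diagnostic-accuracy statistics.
No spectral data from any real cohort is included or required.

## The generative model

Each spectrum is simulated on a wavenumber grid (default 1800–900
cm^-1^, 451 points, i.e. 2 cm^-1^ spacing — the fingerprint region) as

$$
A_{pws}(\nu) \;=\; c_{pw}\sum_k a_k^{(z_p)}
  \exp\!\left(-\frac{(\nu-\mu_k)^2}{2\sigma_k^2}\right)
  \;+\; o_{pw} \;+\; b_{pw}(\nu) \;+\; \varepsilon_{pws}(\nu),
$$

for patient $p$, well $w$, scan $s$. The Gaussian band library
(`default_band_library()`) places six broad bands near 1650, 1540, 1450,
1400, 1240 and 1080 cm^-1^, loosely matching the amide I/II, CH-bending,
carboxylate, amide III/phosphate and carbohydrate/phosphate bands that
dominate dried-serum spectra. Class enters only through the band amplitudes:
for a cancer patient ($z_p = 1$) the designated bands are scaled by
$1 + d_k\,\epsilon$ with `effect_size` $\epsilon$ (default 0.03) and signed
directions $d_k \in \{-1,0,+1\}$. Opposite signs on different bands make the
class difference a change of spectral *shape*, so it survives vector
normalisation; at 3% the class mean spectra are indistinguishable by eye,
which is the regime that motivates a machine-learning read-out in the first
place.

The nuisance terms model the replicate structure:

| parameter | unit | default | role |
|---|---|---|---|
| `mult_scale_sd` | — | 0.05 | $c_{pw}=e^{N(0,\sigma^2)}$, droplet-thickness scaling shared by a well |
| `well_effect_sd` | a.u. | 0.01 | additive offset $o_{pw}$ shared by a well |
| `baseline_amp`, `baseline_order` | a.u., — | 0.05, 2 | random polynomial drift $b_{pw}$ per well |
| `noise_additive_sd` | a.u. | 0.005 | white noise per scan and grid point |

All well-subscripted draws are shared by the three scans of a well, so
within-well spectra correlate more strongly than across wells — the property
that makes spectrum-level cross-validation splits leak and motivates
patient-grouped folds. The cancer count is
`round_half_away(n_patients * prevalence)` (round half away from zero), so
configured prevalences such as 67/385 are hit exactly; tumour subtypes are
apportioned among cancers by largest remainder from a glioblastoma-dominant
mix (34/67). One integer seed makes the whole cohort byte-reproducible.

What the generator deliberately does **not** emulate: between-patient
biological variability (two patients of the same class differ only through
well/scan noise), instrument physics (ATR penetration depth, background-well
subtraction, water-vapour and CO~2~ lines), drying-pattern chemistry, and
any real serum biochemistry. The practical consequence is that the default
synthetic task is *easier* than the clinical one — a consistent 3% band
shift against well-behaved noise is linearly separable at realistic cohort
sizes, and the end-to-end pipeline reaches near-perfect discrimination on
default cohorts. Passing pipeline tests on this generator therefore
demonstrates correctness of the machinery (no leakage, calibrated null,
monotone dose–response in `effect_size`), not clinical performance.

## Preprocessing

The pipeline order is fixed: region selection → baseline correction →
Savitzky–Golay smoothing → normalisation. Normalising last makes the
features scale-free, cancelling exactly the multiplicative droplet-thickness
variation the simulator injects. Defaults are conventional serum-FTIR
chemometrics: fingerprint region 1800–900 cm^-1^, rubberband baseline (the
spectrum minus the linear interpolation of its lower convex hull), no
smoothing, unit-Euclidean-norm ("vector") normalisation. Every stage is
config-switchable; the polynomial baseline subtracts an orthogonal-basis
least-squares fit, and smoothing uses `signal::sgolayfilt`, which reproduces
polynomials of degree at most the filter order exactly, edges included.
"Exactly zero" assertions in the tests use an absolute tolerance of 1e-9.

## Classification and threshold tuning

The published test's classifier is proprietary and undisclosed, so the
package provides two standard families behind one contract — a probability
random forest (`ranger`, the default) and ridge-penalised logistic
regression (`glmnet`) — and makes every claim about the *pipeline and
statistics*, not about any particular model. Cross-validation is always
grouped by patient and class-stratified to within one patient;
`train_classifier()` refuses fold maps that split a patient, and every
reported number downstream is computed from out-of-fold probabilities.

The consensus decision threshold is tuned *after* aggregation, at patient
level, because the test's reported operating point is per patient. Whether
the original threshold was tuned pre- or post-consensus is not public; we
chose post-consensus and treat the alternative as out of scope. The
"balanced" objective maximises min(sensitivity, specificity), breaking ties
by the smaller |sensitivity − specificity| and then the lower threshold; a
constrained objective (maximise sensitivity subject to a specificity floor)
is also provided.

## Consensus votes and ROC sweeping

A spectrum votes "cancer" when its probability is ≥ the threshold
(inclusive, so every ROC point is bit-reproducible). With nine votes the
patient rule is "cancer iff ≥ 5 votes". For patients with $k \ne 9$ usable
spectra the default policy is a strict majority of the available votes with
exact ties resolved to "cancer" — the test's clinical value is its negative
predictive value, so ambiguity must not produce false reassurance; a hard
`error` policy is available instead.

Internally the threshold sweep uses the observation that the consensus calls
"cancer" at threshold $t$ exactly when the patient's $r$-th largest
probability is ≥ $t$ (with $r$ the required vote count), which turns the
consensus ROC into a standard ROC on one score per patient and makes the
monotone stepping of sensitivity and specificity structural rather than
empirical. AUC is computed by the trapezoid rule over
(1 − specificity, sensitivity), which equals pairwise concordance on
tie-free scores.

Under independent per-spectrum votes with accuracy $p$, the patient-level
rate is the binomial tail $\sum_{j\ge5}\binom{9}{j}p^j(1-p)^{9-j}$
(`consensus_accuracy()`); because 5-of-9 is a symmetric majority the same
expression applies to both classes, and it exceeds $p$ whenever $p > 0.5$ —
the quantitative sense in which the nine-replicate design buys accuracy.
`spectrum_accuracy_for()` inverts the tail numerically (e.g. a per-spectrum
accuracy of 0.634 yields a patient-level rate of 0.80).

## Diagnostic statistics

`diagnostic_report()` computes sensitivity, specificity, prevalence, PPV,
NPV and accuracy from the patient-level confusion matrix, each with a
binomial confidence interval on its own denominator. The Wald interval
$p \pm z\sqrt{p(1-p)/n}$ is the default because it is the interval
conventionally printed alongside such tables and reproduces the published
panel cell-for-cell after whole-percent rounding; the Wilson score interval
is available as an option for small samples or boundary proportions, where
Wald coverage is known to oscillate below nominal. Internally
$z = 1.959964$ at 95%; display rounding is to the nearest whole percent for
report tables and one decimal for precision (half-width) values. Zero
denominators yield `NA` plus a warning, never a silent 0. The identity
accuracy = prevalence·sensitivity + (1 − prevalence)·specificity is checked
to 1e-12 in the tests.

Precision and planning calculations treat "precision" as the Wald half-width
in percentage points (`half_width()`), and `required_n()` inverts it to the
smallest total cohort size given an anticipated prevalence, cross-checked in
the tests against a brute-force scan.

Prevalence transport offers two labelled methods, because published figures
of this kind are sometimes computed either way: the textbook Bayes formulas,
and the linear rescaling PPV·π/π~cohort~ (under which NPV is undefined and
returned as `NA`). At sensitivity 54/67, specificity 253/318 and π = 0.03
these give 10.9% and 7.8% respectively; they agree to first order as
π → 0 up to a specificity-dependent constant, and neither is forced to match
any externally printed value in between.

## Problem sizes and reproducibility

The test-suite and acceptance-script simulations use: 300 patients
(balanced classes) across 5 seeds for the null calibration — balanced
classes keep the null-AUC sampling SD near 0.033 so the [0.40, 0.60]
acceptance band is a ≈3σ check; 150–200 patients on reduced grids for the
effect-monotonicity and separability checks; 10,000 simulated patients for
the binomial-tail comparison; and 100 replicates of 67 positive patients for
Wald-coverage of a configured sensitivity of 0.8 (exact coverage there is
92.0%, a known Wald oscillation, which is why the coverage check is a ≥90%
bound rather than 95%). Every random quantity flows from one integer seed;
identical configurations give byte-identical cohorts, and `run_simulate()` /
`run_evaluate()` write config snapshots and logs sufficient to replay a run.

## Known limitations

* No between-patient biological variability, instrument physics or
  atmospheric artefacts in the generator (above): synthetic performance
  numbers are statements about the pipeline, not the assay.
* The classifier families are stand-ins behind the published test's
  interface; no attempt is made to reproduce proprietary weights, the
  724-patient training database, or figure-only quantities such as the
  published ROC AUC.
* Wald intervals can undercover for small $n$ or extreme proportions; use
  `ci_method = "wilson"` in those regimes.
* The linear prevalence rescaling is provided for comparability with
  published practice; the Bayes method is the statistically coherent choice
  and the two are always labelled.
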