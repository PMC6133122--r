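---
title: "Methods: from urine NMR spectra to a kidney-rejection score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from urine NMR spectra to a kidney-rejection score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroNMR)
```

## The problem and the two-phase strategy

Monitoring kidney-transplant recipients for acute allograft rejection
currently relies on serum creatinine and, ultimately, graft biopsy — an
invasive procedure graded histologically on the BANFF scale (category 1
= no rejection, 4 = acute cellular rejection).  `nephroNMR` implements a
pipeline that derives, and applies, a urine `1H`-NMR *metabolite
rejection score* as a non-invasive complement.

The derivation runs in two phases:

1. **Binned-spectrum discovery.**  Spectra are referenced, baseline
   corrected, quality controlled, cut into equal-width bins,
   total-integral normalized, cubic-root transformed and autoscaled.
   Iterative random-forest feature selection with programmatic
   bin-quality flags reduces 377 bin features to a handful of candidate
   signal regions.
2. **Quantified-metabolite modelling.**  A fixed panel — alanine,
   citrate, dimethylamine (DMA), glucose, glucuronate, hippurate,
   lactate, phenylacetylglutamine (PAQ), trigonelline, urea, plus
   creatinine for urine-concentration normalization — is quantified by
   pseudo-Voigt peak fitting with goodness-of-fit gating.  All
   $\sum_{i=1}^{5}\binom{10}{i} = 637$ logistic models of up to five
   metabolites are fitted and filtered by cross-validated training AUC,
   test-set AUC under two labeling settings, and an ordered list of
   declarative judgment rules, down to the final four-metabolite model.

The final model computes, per sample,

$$\omega = \beta_0 + \beta_{ala} I_{alanine} + \beta_{cit} I_{citrate} +
  \beta_{lac} I_{lactate} + \beta_{urea} I_{urea}, \qquad
  Score = \frac{100}{1 + e^{-\omega}}$$

where $I_x$ is the creatinine-normalized, log-transformed, centered and
scaled intensity of metabolite $x$, and the shipped coefficients are the
published constants ($\beta_0 = -3.0048615$, $\beta_{ala} = -0.2527461$,
$\beta_{cit} = -0.8224731$, $\beta_{lac} = +0.9502339$,
$\beta_{urea} = +0.2529190$).  Rejection pushes lactate and urea up and
alanine and citrate down, so the score rises with rejection likelihood.

## Case/control labeling

A sample taken within 7 days before a biopsy (day of biopsy included,
day $-7$ included) inherits that biopsy's outcome: BANFF 4 (alone or in
conjunction with other categories) labels it *case*; BANFF 1 labels it
*control*; isolated BANFF 2/3/5 *exclude* it.  Training-cohort samples
without an attached biopsy are controls when the patient was never
biopsied or had only negative biopsies, excluded otherwise.  Test
cohorts support a *strict* setting (biopsy-linked samples only) and an
*extended* setting (unbiopsied samples additionally count as controls).
Only *late-phase* samples (day $\ge 15$ post transplant, transplant day
= day 0) enter modelling; early samples are prone to hematuria
interference.  Where the source material states "at least 14 days" in
one place and "day $\ge 15$" in another, this package adopts $\ge 15$.
When several biopsies fall in a sample's window the nearest wins, a tie
going to the later biopsy — a deliberate convention, since no rule is
documented.

## The synthetic-data generator

No clinical cohort is distributed with this problem, so the package
ships a generator whose defaults are its fixed study conditions:

* 180 patients, 8–12 urine samples each (about 1800 samples), matching
  the scale of a realistic single-center training cohort;
* per-patient rejection prevalence 0.15; a rejecting patient carries a
  rejection episode on a random post-transplant day, receives a BANFF-4
  biopsy with probability 0.9, and two sampling days in the week before
  the episode are always present so biopsy-linked case samples exist;
  non-rejecting patients are biopsied (BANFF 1) with probability 0.1;
* log-normal metabolite concentrations (log-sd 0.4, per-patient random
  effect sd 0.15) with case shifts proportional to the published
  coefficients: alanine $-0.25$, citrate $-0.82$, lactate $+0.95$, urea
  $+0.25$ in standardized units.  Under these shifts the large-sample
  AUC of the true score is about 0.8 — the same performance regime the
  published model operates in;
* spectra on a uniform grid ($-0.5$ to $10$ ppm, step $5\times10^{-4}$
  ppm): pseudo-Voigt multiplets (shared FWHM 0.003 ppm, mixing fraction
  0.5) with areas proportional to concentration, a TSP reference
  singlet at 0.0 ppm, a polynomial baseline, a broad residual-water
  Lorentzian at 4.75 ppm, and i.i.d. Gaussian noise.

Metabolite positions and splittings (e.g. alanine doublet at 1.48 ppm,
lactate doublet at 1.33 ppm, citrate AB system around 2.5–2.7 ppm,
creatinine singlet at 3.045 ppm) are literature-standard values at
600 MHz, shipped as `inst/extdata/signal_templates.csv`.  They are
project constants: the source publication never printed the positions
it quantified.  The glucose and glucuronate templates share one fit
window by design, because their signals neighbour each other and must
be quantified simultaneously.

**What the generator does not emulate** — and hence what passing tests
cannot show about real data: pH-dependent chemical-shift drift,
J-coupling fine structure beyond fixed multiplet splitting, baseline
distortions from imperfect water suppression, between-instrument
calibration differences, urine matrix effects, and, most importantly,
the real covariance structure of urinary metabolites in transplant
patients.  Passing the pipeline on synthetic cohorts demonstrates the
*correctness of the machinery*, not the clinical performance of the
score.

## Numerical and design choices

* **Binning geometry.**  The published bin count (377) is documented
  but not its geometry.  The default here is 0.716–9.516 ppm in
  0.022-ppm bins: the residual-water region 4.5–5.0 ppm then falls
  exactly on bin edges, its 23 bins are dropped, and 377 bins remain.
  The count is asserted by a configuration-conformance test, never
  hard-coded.
* **Cubic root of negatives.**  Bins can go slightly negative after
  baseline correction; the signed real root is used.
* **Autoscaling and feature standardization** are estimated on training
  data only and frozen for test data — required for honest test-set
  AUC.
* **Baseline correction** is an asymmetric-least-squares smoother
  (second-difference penalty, stiffness $\lambda = 10^7$ on a 4-fold
  thinned grid, 8 reweighting iterations).  Points more than two noise
  sd above the current baseline are down-weighted to $p = 0.001$;
  points inside the noise band keep full weight, so the baseline runs
  through the middle of the noise rather than its lower envelope.  The
  penalty's null space contains constants and linear trends, which are
  therefore removed exactly.
* **Peak fitting** is bounded Levenberg–Marquardt least squares of the
  template multiplet plus a local linear background, restarted from
  three starting centers (deterministic).  Goodness of fit is the RMS
  residual normalized by the in-window amplitude; the default gate is
  0.05 (a project constant — no threshold is documented).  A fit is
  invalid on non-convergence, a gof above threshold, or area, center or
  width pinned at a bound; the mixing fraction may legitimately sit at
  0 or 1 and is not bound-checked.
* **Cross-validation** is patient-grouped (5-fold, 10 repeats by
  default): repeated samples from one patient never straddle a fold,
  preventing leakage.  Whether the original analysis grouped by patient
  is undocumented; grouping is the defensible choice.  One shared fold
  seed is used across all 637 candidates so that paired model
  comparisons contrast identical held-out splits.
* **AUC** uses the tie-aware Mann–Whitney convention (half credit);
  confidence bands use stratified bootstrap (2000 draws) via pROC.
* **The "manual" filtering rules** (drop trigonelline for coffee
  confounding, require lactate, prefer alanine over hippurate, drop
  DMA, glucose and glucuronate) are encoded as an ordered, editable
  rule list (`default_filter_rules()`) — reproducible data, not code,
  since they are judgment calls rather than statistics.
* **AUC thresholds** 0.75 (training, cross-validated) and 0.70 (test,
  per setting) are inclusive, mirroring the published cascade.
* **Degenerate inputs.**  Zero-integral spectra, zero-variance bins and
  failed creatinine fits are flagged, never silently imputed; a sample
  without valid creatinine is unusable, since normalization is
  impossible.

## Problem sizes used by the test suite

The package chooses deliberately scaled simulation sizes: parameter
recovery uses 50,000 feature rows (Monte-Carlo standard error of each
slope about 0.02); moment-fidelity checks use cohorts of about 2,000
samples; the end-to-end spectral run uses 20-patient cohorts
(~200 spectra across train and test); the core-vs-noise model ranking
repeats 20 seeds of 60-patient cohorts at the concentration level.
These sizes keep every property detectable at its stated tolerance
while the whole suite completes in minutes.

## Known limitations

* The published training cohort's standardization constants behind
  $I_x$ were never released, so applying the exact published
  coefficients to new raw data is impossible in principle; any fitted
  model produced by this package carries its own standardization, and
  the shipped published-model file carries none.
* The real data-flow counts and AUCs (e.g. training AUC 0.76) are not
  reproducible without the unreleased cohort; the pipeline reproduces
  the logic and, on synthetic cohorts, the performance regime.
* Phase correction and between-device calibration transfer are out of
  scope; synthetic spectra are generated in pure absorption mode.
* The JCAMP-DX reader supports only the uncompressed `(XY..XY)`
  point-pair form.
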