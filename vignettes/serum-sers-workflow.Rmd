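---
title: "Serum SERS chemometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum SERS chemometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersdx)
```

This vignette is the package's account of its science: what each stage
models, which parameters matter and why their defaults are what they
are, what the synthetic cohort does and does not emulate, and where the
design was genuinely open.

## The diagnostic problem

Serum SERS spectra of gallbladder-stone patients, gallbladder-polyp
patients and healthy controls share nearly identical profiles; the
diagnostic signal is a set of small, correlated intensity shifts at a
few biochemically interpretable bands (amino acids, coenzyme A, sugars,
lipids) riding on a large, sample-specific autofluorescence background.
The workflow therefore has three jobs: remove variation that carries no
class information (noise, baseline, overall intensity), model the class
structure in the remaining 601-dimensional signal, and quantify how much
of the apparent separation would survive on unseen samples.

## Preprocessing

**Savitzky–Golay smoothing** (default: 9-point window, degree-5
polynomial) replaces each point by a local least-squares polynomial
value; it suppresses shot noise while preserving band shape because any
polynomial of degree ≤ 5 passes through unchanged. Endpoints are handled
by the polynomial fit within the terminal window. A degree that high in
a 9-point window smooths very gently; users with noisier instruments
should widen the window before lowering the degree.

**airPLS baseline removal.** The baseline is the solution of a weighted
Whittaker smoother with a second-difference penalty λ (default 10⁴,
dimensionless; larger = stiffer baseline). Weights are re-estimated each
iteration: zero where the spectrum exceeds the baseline (peak regions),
exponentially increasing with the magnitude of negative residuals
elsewhere, so the baseline settles onto peak-free support. Iteration
stops at 15 rounds or when the summed negative-residual magnitude falls
below 0.1% of the total absolute intensity. On the synthetic cohort's
baseline shapes, recovery is well inside 5% RMS away from peak cores
across the λ range 10³–10⁵; results are only mildly λ-sensitive, and
λ = 10⁴ sits in the middle of that plateau. Negative intensities after
subtraction are retained — clipping would bias the normalization that
follows.

**Vector normalization** divides each spectrum by its Euclidean norm,
removing sample-to-sample intensity scale (colloid batch, focus,
integration time). It has a side effect worth knowing: because the norm
is computed from the whole spectrum, a class whose band intensities are
systematically higher *overall* will show small compensating shifts at
bands that carry no true effect. The synthetic generator's default
effects are deliberately balanced per class so that null bands stay null
after normalization (see below).

The stage order — smooth, baseline-correct per spectrum, normalize — is
fixed; replicate averaging happens before any of it, at acquisition
level, matching the measure-five-times-and-average convention.

## The synthetic cohort

`generate_cohort()` emulates the study conditions the analysis is
designed for: 72 healthy / 51 stone / 25 polyp samples, a 600–1800 cm⁻¹
grid at 2 cm⁻¹ (the stated acquisition range; the step is our choice, as
instrument resolution is not part of the design), 11 Lorentzian bands
(FWHM 16 cm⁻¹ — a typical solution-phase Raman linewidth) at the
characteristic serum wavenumbers, a broad Gaussian fluorescence hump
(centre 1300 cm⁻¹, FWHM 600 cm⁻¹, amplitude ≈ 2× the strongest band)
plus a linear tilt, both drawn per sample (lognormal, σ = 0.2), additive
Gaussian noise (σ = 0.03 per replicate point), five replicates averaged
per sample, and per-sample, per-band lognormal amplitude jitter
(σ = 0.15) creating within-class spread.

Class effects are encoded as band multipliers with the qualitative
directions reported for this disease setting — stone depressed at
888 cm⁻¹, polyp elevated at 1203 cm⁻¹, stone ≠ polyp at 637, 722, 1203,
1432 and 1652 cm⁻¹, polyp ≠ healthy additionally at 1134 cm⁻¹ — and no
effect at 810, 1003, 1333 and 1557 cm⁻¹. No published effect *sizes*
exist for these shifts, so magnitudes (16–40%) were chosen once to give
realistic, comfortably detectable but not trivial separations, and are
fully configurable (`default_serum_bands(effect_scale = ...)` scales the
log-multipliers; 0 removes all effects). Within each class the
amplitude-weighted multiplier deviations approximately cancel, keeping
total band intensity balanced across classes — without this, vector
normalization converts an overall intensity difference into spurious
effects at null bands.

What the generator does **not** emulate: band-position shifts,
width/shape changes, correlated (pink) noise, cosmic-ray spikes,
batch/drift structure, or any covariance between bands beyond the shared
jitter. Passing tests on this cohort therefore demonstrate correctness
of the algorithms and recoverability of multiplicative band effects —
not clinical performance on real serum, where those nuisances exist and
effect sizes are unknown.

## OPLS-DA

The model is fitted from first principles. The dummy response Y has one
indicator column per class; X is mean-centered only (no unit-variance
scaling — after vector normalization all variables share one scale, and
scaling would inflate baseline-residual regions; `scale = TRUE` is
available). Each orthogonal component takes a candidate NIPALS loading,
projects it off the span of XᵀY, and deflates X by the resulting score;
its scores are exactly uncorrelated with every Y column by construction.
Predictive components are then standard NIPALS PLS2 with deflation.

Component counts: the triple-class model uses 2 predictive components
(classes − 1); binary models use 1. The orthogonal count defaults to a
user choice (the workflow uses 1); `n_orthogonal = "auto"` adds
components while cross-validated Q² improves by > 0.01, capped at 5.
Q²(cum) uses the cumulative-product convention
1 − Π₍ₐ₎ PRESSₐ/SSₐ₋₁ with PRESS pooled over stratified 10-fold CV
(seeded, recorded in the model); the simpler 1 − PRESS/SS convention
coincides for one component. We deliberately use 10 folds, not SIMCA's
internal default of 7, because 10-fold CV is the stated assessment
protocol of this workflow.

Multiclass discrimination is a single OPLS model on the 3-column dummy
response (giving one joint score plot), not one-vs-one models.
Prediction reconstructs the dummy estimates and assigns the class of the
maximum; exact ties fall to the first class in order, with a warning.

## PCA-LDA

The comparison classifier reduces X by centered SVD and keeps the
smallest number of components explaining ≥ 95% of variance, capped at
n/3 (LDA needs far fewer observations per parameter than 601 variables
would demand; the cap keeps the pooled scatter well-conditioned). LDA
uses equal priors — a diagnostic convention: prevalence in a case-control
cohort is a sampling artefact — and is never fitted on raw spectra.
Which classifier wins is data-dependent; on strongly separable synthetic
cohorts they tie, so the package reports both rather than asserting an
ordering.

## Validation and metrics

Stratified k-fold CV predicts every sample exactly once out-of-fold;
the pooled confusion matrix is the honest performance summary.
Training-set reports and ROC curves are also produced (they match common
published practice) but are labelled as such; out-of-fold ROC is
recommended.

The permutation test refits the model on 100 row-permutations of Y,
records R²Y and Q² against the mean absolute column-wise correlation
between permuted and original Y, and regresses both (including the
original model at correlation 1). Intercepts below 0.4 (R²) and 0.05
(Q²) flag a well-constructed model; these thresholds are the published
convention this workflow adopts.

Two specificity conventions circulate in multiclass diagnostic tables.
The standard one-vs-rest TN/(TN+FP) is reported as
`specificity_standard`. The headline `specificity` uses the
diagnostic-table convention — among out-of-class samples, the fraction
assigned to *their own* correct class — because that is the definition
consistent with published benign-gallbladder confusion tables this
package reproduces in its acceptance checks. Percent metrics are
rounded half-up at one decimal, matching table conventions. AUC is the
Mann–Whitney rank statistic (ties count ½), invariant under monotone
score transforms.

## Peak analysis

Peak intensity is the maximum within ±8 cm⁻¹ of the nominal position
(robust to small calibration shifts; the window is four grid steps each
side). Group comparison is fixed-effects one-way ANOVA per peak at
α = 0.05 with no multiplicity correction — the convention for small
fixed peak panels — with a Bonferroni column emitted alongside for
transparency.

## Numerical choices and degenerate inputs

* Whittaker systems are solved sparsely (banded Cholesky via Matrix);
  dense solves agree to 10⁻⁹ on short vectors.
* NIPALS iterates to a 10⁻¹² relative score change, capped at 500
  rounds; a collapsed weight norm (< 10⁻¹⁴) raises a degenerate-data
  error rather than returning noise.
* Orthogonal extraction stops with an error when no Y-uncorrelated
  variation remains (projection norm < 10⁻¹²).
* All-zero spectra cannot be normalized and are rejected by sample id;
  non-finite intensities are rejected at container construction.
* Fold counts above the smallest class size, degenerate (zero-variance)
  X, and fewer than 3 samples per class are errors, not warnings.
* Every stochastic step (cohort generation, CV splits, permutations)
  takes an explicit integer seed; fixed seed ⇒ bit-identical results.

## Problem sizes

The packaged workflow and tests run the full 148-sample, 601-point
cohort for cohort-level checks (ANOVA recovery over 20 seeds,
100-permutation validation) and smaller cohorts (42 samples) or tiny
matrices (8×5) where the point is oracle equivalence rather than power.
These sizes were chosen so the whole suite exercises every code path in
a few minutes while keeping the statistical checks well-powered.

## Known limitations

* Effect sizes are invented (directions only are anchored); absolute
  performance numbers on synthetic cohorts say nothing about clinical
  accuracy.
* The airPLS λ default suits smooth fluorescence humps on this grid;
  sharply curved baselines need smaller λ.
* Orthogonal-component auto-selection is greedy and can stop early near
  the 0.01 Q² improvement threshold.
* No DeLong confidence intervals on AUC, no calibration analysis, no
  batch-effect modelling.
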