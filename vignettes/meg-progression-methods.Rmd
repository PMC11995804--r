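---
title: "Spectral and Riemannian MEG biomarkers of MCI-to-AD progression: methods"
author: "megprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral and Riemannian MEG biomarkers of MCI-to-AD progression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megprog)
```

# The problem

Patients with mild cognitive impairment (MCI) differ in whether they later
progress to Alzheimer's disease (AD) dementia. Resting-state
magnetoencephalography (MEG) offers non-invasive candidate biomarkers of
that risk: frequency-resolved power, sensor covariance, phase coupling and
power-envelope coupling. `megprog` implements a complete analysis chain for
a two-site MCI cohort (64 progressors, 53 stable; sites "CTB" and "CBU"
with a strongly imbalanced 41/49 vs 23/4 progression split), together with
a synthetic-cohort generator so that every stage of the chain is testable
without any patient data.

The pipeline has six stages:

1. **Cohort simulation** — epoched magnetometer signals plus demographics,
   MMSE, and regional MRI volumes with planted group effects.
2. **Wavelet spectral metrics** — power spectral density, covariance,
   debiased squared weighted phase-lag index (dwPLI) and power-envelope
   correlation on one common Morlet representation.
3. **Riemannian statistics** — affine-invariant distances between
   rank-reduced SPD matrices, tangent-space embedding, and a
   frequency-wise permutation distance MANOVA.
4. **Cluster inference** — threshold-free cluster enhancement (TFCE) with
   max-statistic permutation correction across frequency and
   sensor-by-frequency maps.
5. **Additive logistic risk models** — four nested models of progression
   with AIC comparison, average marginal effects, and bootstrap
   discrimination metrics.
6. **Stacked classification and conditional permutation importance
   (CPI)** — modality-wise ridge classifiers cross-fitted into a
   regularized logistic combiner under repeated, stratified
   cross-validation, with a Nadeau–Bengio-corrected importance test.

# The wavelet representation

All spectral metrics share one family of complex Morlet wavelets on a
base-2 logarithmic grid: centre frequencies run from `fMin` = 1 Hz to
`fMax` = 64 Hz in steps of 0.05 octaves (121 wavelets); the spectral
smoothing is 0.35 octaves. The Gaussian envelope is parameterized by the
**half-power convention**: the kernel's squared transfer function falls to
one half of its peak at $f\,2^{\pm b/2}$, giving

$$\sigma_f = \frac{f\,(2^{b/2} - 2^{-b/2})}{2\sqrt{\ln 2}},
\qquad \sigma_t = \frac{1}{2\pi\sigma_f}.$$

The Gaussian is symmetric in linear frequency while octave edges are not,
so the two measured edge gains straddle $1/\sqrt2$ with their geometric
mean on it; the test suite pins this down numerically. Kernels are
truncated at $\pm 5\sigma_t$ and normalized to unit spectral peak gain;
the truncation halfwidth doubles as the edge-invalidation halfwidth, and
coefficients inside it are excluded from every downstream average. A
frequency whose halfwidth exceeds half the epoch is flagged unusable and
dropped — with 10-s epochs this is exactly the low-frequency regime where
envelope statistics become unstable.

Power is reported as a one-sided density in units²/Hz by dividing the
mean squared coefficient by the kernel's noise-equivalent bandwidth
(computed numerically from the kernel FFT) and doubling; band integration
is done over Hz with the trapezoid rule, which preserves the 1/f shape of
the background. Covariance is the real part of the averaged outer product
of coefficients (its diagonal is the unscaled power). dwPLI uses the
debiased estimator
$[(\sum I)^2 - \sum I^2]/[(\sum|I|)^2 - \sum I^2]$ with
$I_j = \mathrm{Im}(X_j \bar Y_j)$; a zero denominator (no imaginary
cross-spectrum, e.g. identical signals) is reported missing rather than
zero. The power envelope is $\log(|c| + \varepsilon)$ with
$\varepsilon = 10^{-12}$ times the median coefficient magnitude — a
numerical guard only — and envelope correlation is the Pearson
correlation over valid samples pooled across epochs. Pooling every valid
sample (rather than per-epoch averages) is the package's single documented
observation-unit convention; it maximizes the effective sample count on
2-minute recordings.

# Riemannian machinery

Sensor covariance and envelope-correlation matrices live on the SPD
manifold. Because Maxwell-filter-style preprocessing reduces data rank in
real recordings, matrices are first projected to the dominant common
subspace: the spatial filters are the top-$r$ eigenvectors of the
grand-average matrix ($r = 65$ at full sensor count; eigenvector signs
fixed by the largest-component-positive convention so results are
platform-stable), followed by a trace-scaled jitter of $10^{-15}$.
dwPLI matrices are not SPD; they are repaired by eigenvalue clipping (the
Frobenius-nearest PSD matrix) after filling missing entries with zero,
then projected at aggressive low rank ($r = 5$ at full sensor count).

Group inference uses the affine-invariant Riemannian metric
$\delta(A,B) = \|\log(A^{-1/2} B A^{-1/2})\|_F$, which is blind to any
common linear mixing of the sensors — head-position differences and field
spread act approximately this way. The frequency-wise test is a
permutation distance MANOVA: the pseudo-F from the Gower decomposition of
squared pairwise distances, a permutation p-value with the
$(b+1)/(n_{\mathrm{perm}}+1)$ convention (default 1000 permutations), and
Benjamini–Hochberg FDR across frequencies. The Fréchet mean for
tangent-space embedding is computed by the matrix-log fixed point with
step-size damping (the step is halved whenever its norm grows), tolerance
$10^{-8}$, at most 50 iterations; damping matters in exactly the
ill-conditioned low-frequency envelope regime noted above. Tangent
vectors scale off-diagonals by $\sqrt2$ so Euclidean norms match
Frobenius norms.

# Cluster inference

Pointwise statistics are two-group pooled-variance t (and its square, the
one-way F). TFCE integrates cluster extent$^E$ × height$^H$ over 50
height steps with the standard $E = 0.5$, $H = 2$; connectivity is
frequency-neighbour in 1-D and "same frequency & adjacent sensors, or
same sensor & neighbouring frequency" in 2-D. Two-tailed testing enhances
the positive and negative parts of the signed t-map separately and uses
the maximum over the combined map for the permutation null, which
controls the family-wise error rate by construction; calibration is
verified empirically in the acceptance suite. Covariates (MMSE, site)
can be removed by per-point linear residualization before testing.

# Risk models

The four additive logistic models are
`progression ~ age + education + MMSE` (+ hippocampal ratio, + cluster
MEG power, + both). Predictors are z-scored; fits are maximum likelihood
(IRLS, tolerance $10^{-8}$, max 100 iterations) with an explicit
perfect-separation check that names the culprit predictor. The predictor
count is capped at 5 (20% of the smaller class of 27). The "cluster MEG
power" variable is the mean log10 power over the posterior-and-significant
sensor set within 16–38 Hz, falling back (flagged) to the full
posterior × band mask when no significance mask is supplied. Education
and MMSE gaps are filled by grand-mean imputation; subjects missing the
whole MRI block are excluded from the MRI models rather than imputed,
leaving 104 of 117 under the default missingness pattern.

Discrimination is in-sample (apparent) AUC by the rank statistic, with a
2000-iteration bootstrap in which the model is **re-fitted on every
resample**; paired model comparisons reuse identical bootstrap indices.
Because no operating threshold is stated for sensitivity/specificity,
both the Youden-optimal and the 0.5 threshold values are reported —
cross-validated discrimination belongs to the stacked model, not here.

# Stacked classification

Nine blocks enter the stack: site, age, sex, education, MMSE (scalars),
MEG covariance and envelope correlation (rank-reduced tangent vectors at
every 4th wavelet frequency, 31 of 121), dwPLI (upper-triangle vectors),
and 64 regional MRI volumes. First-layer models are L2-regularized
least-squares classifiers on ±1 targets whose penalty is selected by
generalized cross-validation over 50 log-spaced values in
$[10^{-3}, 10^5]$ — computed exactly from one SVD per fit. The second
layer is a ridge-penalized logistic model over the nine cross-fitted
scores with leave-one-group-out internal validation, the groups being the
first-layer folds, so no subject is ever scored or combined by a model
that saw it. Under the default 10×10 stratified scheme this yields 100
held-out AUCs per model; marginal single-block models are evaluated on
identical splits. Iterative (round-robin ridge) imputation and
standardization are fitted on training folds only; tangent references
(Fréchet means) are likewise computed per training fold. Fold bookkeeping
is guarded by hard assertions that trip on any corrupted assignment.

CPI perturbs, per variable and CV split, only the information not
explained by the other eight variables: a ridge model fitted on training
rows predicts the variable, and test-row residuals are permuted (500
draws by default) and re-added before the second-layer log loss is
re-evaluated. The cross-fitted pseudo-t divides the mean loss increase
across splits by its SD with the Nadeau–Bengio variance inflation
$\sqrt{1/K + \rho}$, $\rho = n_{\mathrm{test}}/n_{\mathrm{train}} =
1/(k-1)$ for $k$-fold, $df = K - 1$, one-sided (removing information is
expected to hurt). No multiplicity correction is applied across the nine
variables, as the conditional construction already controls type-1 error
per variable.

# The synthetic cohort

The generator is the package's definition of the study conditions, not a
fixture. Defaults: 64/53 split over CTB 41/49 and CBU 23/4; group-wise
Gaussian demographics (progressors: age 73.03 (6.98), education 10.24
(4.54), MMSE 25.54 (2.82) clipped to the observed 17–30 range; stable:
72.47 (5.32), 8.58 (4.50), 27.15 (2.41) clipped to 22–30; sex simulated
at the observed proportions but given no effect on signals); 12 × 10 s
epochs at 250 Hz on 102 sensors; missingness 15 education / 5 MMSE / 13
whole MRI blocks.

Signals are a mixed sum of: per-sensor 1/f background (spectral shaping
of white noise, exponent 1); a posterior ~10 Hz alpha source; a posterior
16–38 Hz source whose amplitude is multiplied by
$1 - \texttt{betaPowerReduction}$ (default 0.3) in progressors; a
delta–theta source pair whose sources are correlated by
`lowfreqCovShift` (default 0.5) in progressors with per-sensor power
rescaled to match — a pure covariance effect; a ~9 Hz pair with a fixed
90° phase lag whose coupling is weakened by `alphaPlvShift` (default
0.3); and a 13–17 Hz pair with shared slow amplitude modulation weakened
by `envCorrShift` (default 0.3). Band-limited sources are 4th-order
Butterworth band-passes of white noise; mixing vectors are spatially
smooth random fields over the layout, shared across the cohort (as shared
anatomy implies) with a 0.4 per-subject jitter, and posterior-weighted
sources leak weakly (0.1) to non-posterior sensors to mimic field
spread. Subjects carry lognormal amplitude variability (global gain
sdlog 0.1; per-source gains sdlog 0.25) — the dominant between-subject
factor in resting M/EEG. These constants were chosen so that the
posterior-band log-power summary separates the groups at about one
pooled SD in the default cohort, matching the strength of a posterior
beta effect that is robust at n = 117 but far from trivial. With all
four effect sizes at zero the group label does not enter signal
generation at all, which is what makes the null-calibration suites
meaningful.

MRI: the hippocampal-to-total-grey-matter ratio is drawn at 0.0050
(0.0007) in progressors vs 0.0055 (0.0007) in stable patients —
consistent with a ~7 cm³ hippocampus over ~600 cm³ grey matter and
hippocampal atrophy in converters — and the ratio times total grey
matter is volume 1 of the 64-region block. The remaining 63 regions are
drawn with a 6% lower mean in progressors (per-region effect ~0.3 SD),
reflecting the distributed cortical atrophy of converters; without some
distributed signal a 64-column block cannot reach the marginal
discrimination that real cortical volumes show, and the hippocampal
column alone would leave the MRI block near chance.

What the generator does **not** emulate: biophysical forward fields,
ocular/cardiac artefacts, site-specific hardware noise, follow-up-time
structure, or any dependence between demographics and signals. Passing
tests therefore demonstrate the correctness and calibration of the
machinery under a controlled data-generating process — not clinical
performance on real MEG.

# Numerical and design choices

* Wavelet bandwidth is defined by the half-power convention above; the
  package states it explicitly so results can be compared against other
  toolchains that may define bandwidth differently.
* SPD regularization is `reg × trace/dim` with `reg = 1e-15`; if a
  projected matrix still fails strict positive definiteness the whole set
  receives the minimal common diagonal shift (deterministic, recorded in
  the object).
* Permutation p-values always use the $(b+1)/(n+1)$ convention and are
  floored at $1/(n_{\mathrm{perm}}+1)$.
* The direction of the low-frequency covariance effect is a free
  parameter of the generator (progressors' delta–theta sources become
  correlated); the analyses only claim that *a* covariance difference
  with matched power is detectable, not its direction.
* Serialization: cohort tables as CSV (empty field = missing), layout as
  JSON, per-subject signal arrays as RDS with sampling attributes.
* Pipeline reproducibility: one global seed fans out to fixed per-stage
  substreams; identical configurations produce byte-identical result
  tables, and the run manifest records a config hash and wall times.

# Problem sizes used by the test and acceptance suites

Simulation-backed checks run at reduced sizes chosen once: calibration
suites use 16 subjects × 4×4 SPD sets (distance MANOVA), 20 subjects ×
16 sensors × 10 frequencies (TFCE FWER), and 60 subjects × 5 score
columns (CPI), with 150–300 replicates each; the recovery suite keeps
the full 64/53 split but 24 sensors, 3 × 5 s epochs at 128 Hz and nine
wavelets over 8–45 Hz; risk-model and stacking replicates use 16-sensor
cohorts. The full-scale defaults (102 sensors, 121 wavelets, 10×10 CV)
are the package defaults and run unchanged on a workstation.

# Known limitations

* The stacked model's absolute AUCs depend on the generator's planted
  effect sizes; only orderings and calibration are meaningful claims.
* In-sample AUC with bootstrap CIs is reported for the logistic models by
  design; it is optimistic relative to cross-validation.
* Envelope correlations at the lowest usable frequencies are estimated
  from few effective samples; the rank projection plus damped Fréchet
  iteration keeps the Riemannian path numerically stable, but those
  frequencies remain the least reliable.
* The generator's sources are stationary within epochs; real MEG is not.
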