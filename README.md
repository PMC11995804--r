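# megprog

Spectral and Riemannian MEG biomarkers of progression from mild
cognitive impairment (MCI) to Alzheimer's disease (AD) dementia.

`megprog` is an R package for researchers modelling AD-progression risk
from resting-state magnetoencephalography. It implements, end to end:

* a **synthetic two-site MCI cohort generator** (64 progressors / 53
  stable, sites CTB 41/49 and CBU 23/4) producing epoched magnetometer
  signals with planted effects — a posterior 16–38 Hz power reduction in
  progressors, a low-frequency covariance shift with matched per-sensor
  power, weakened ~9 Hz phase coupling and envelope coupling — plus
  demographics, MMSE, regional MRI volumes and the study's missingness
  pattern (15 education / 5 MMSE / 13 whole MRI blocks);
* **Morlet wavelet spectral metrics** on a base-2 logarithmic grid
  (1–64 Hz, 0.35-octave smoothing, 0.05-octave step, 121 wavelets):
  power spectral density, sensor covariance, debiased squared weighted
  phase-lag index (dwPLI), and power-envelope correlation
  (log-rectified coefficients);
* **Riemannian SPD statistics**: common-subspace rank reduction (rank
  65; rank 5 after nearest-SPD repair for dwPLI), the affine-invariant
  distance `δ(A,B) = ||logm(A^{-1/2} B A^{-1/2})||_F`, tangent-space
  embedding around the Fréchet mean, and a frequency-wise permutation
  **distance MANOVA** (Gower pseudo-F, FDR across frequencies);
* **TFCE cluster-permutation inference** over frequency and
  sensor × frequency maps (E = 0.5, H = 2, max-statistic null,
  two-tailed, optional covariate residualization);
* the four additive **logistic risk models**
  `progression ~ age + education + MMSE (+ hippocampal ratio)
  (+ cluster MEG power)` with AIC comparison, average marginal effects
  (delta-method z-tests), and bootstrap AUC with refit per replicate;
* a **stacked classifier**: per-modality ridge classifiers with
  GCV-selected penalties cross-fitted under repeated stratified 10-fold
  CV into a regularized logistic combiner (leave-one-group-out over
  folds — no leakage), and **conditional permutation importance** with
  the Nadeau–Bengio corrected one-sided test.

## Worked example

```r
library(megprog)

# statistics that are pure functions of the printed cohort tables
chi2Yates(matrix(c(41, 23, 49, 4), 2, 2))$statistic   # 11.61291
pooledTFromSummary(25.54, 2.82, 64, 27.15, 2.41, 53)$t # -3.280545

# a reduced synthetic cohort with the default planted effects
spec <- cohortSpec(nSensors = 16, nEpochs = 2, epochLenS = 4, fs = 96,
                   seed = 7)
coh <- injectMissingness(simulateCohort(spec))

fam <- buildWaveletFamily(14, 40, 0.35, 0.3, fs = 96)
tab <- cohortTable(coh)
logPsd <- lapply(tab$subject_id, function(id)
  computePower(convolveEpochs(subjectSignals(coh, id), fam))$logPsd)
tab$cluster_meg_power <- as.numeric(
  clusterMegPowerVariable(logPsd, frequencies(fam), coh@layout))

fits <- fitRiskModels(tab)
fits$aic
#>         model       aic   n
#> model1 model1 147.20526 117
#> model2 model2 119.28077 104
#> model3 model3 123.91489 117
#> model4 model4  99.04887 104
round(vapply(fits[1:4], function(f)
  rocAuc(predict(f$model, type = "response"), f$y), 1.0), 3)
#> model1 model2 model3 model4
#>  0.744  0.813  0.844  0.887
averageMarginalEffects(fits$model4)
#>            variable    ame    se    z       p
#> 1               age -0.051 0.036 -1.4 1.5e-01
#> 2         education  0.126 0.031  4.1 4.6e-05
#> 3              mmse -0.140 0.033 -4.2 2.4e-05
#> 4 cluster_meg_power -0.205 0.039 -5.2 1.7e-07
#> 5 hippocampal_ratio -0.125 0.037 -3.4 6.5e-04
```

Reading: adding MEG posterior 16–38 Hz power (model 3) and the
hippocampal/total-grey-matter ratio (model 4) lowers the AIC well below
the demographic baseline, and both carry significant negative marginal
effects — higher posterior beta power and larger relative hippocampus
each reduce predicted progression risk, conditional on age, education
and MMSE. The positive education effect reflects the deliberate
site–education confound built into the cohort. The absolute numbers are
properties of the synthetic generator, not of any patient data.

The full pipeline (simulate → features → stats → model → classify →
cpi) runs from one configuration:

```r
runPipeline(defaultRunConfig(seed = 1), "megprog-run")
```

or from a shell via `inst/scripts/megprog-cli.R run-all --out megprog-run`.

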