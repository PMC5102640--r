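# fnirstbi

Prefrontal hemodynamic biomarkers of traumatic brain injury (TBI) from
continuous-wave functional near-infrared spectroscopy (fNIRS).

## The problem

Chronic TBI alters the prefrontal hemodynamic response to cognitive load.
fNIRS measures that response non-invasively: a forehead pad of light
sources and detectors (16 channels, two wavelengths, 730 and 850 nm,
sampled at 2 Hz) records intensity changes that reflect oxy- and
deoxyhemoglobin (HbO/HbR) concentration changes in the cortex underneath.
This package implements, as a tested and reusable pipeline, a complete
analysis that turns such raw recordings into a classification of subjects
as TBI or healthy:

1. **Optics** — intensity normalization against a baseline window,
   optical-density change ΔOD(t) = −log₁₀ I(t)/Ī₀, and inversion of the
   modified Beer–Lambert law
   ΔOD_λ = (ε_λ,HbO ΔHbO + ε_λ,HbR ΔHbR) · d · DPF_λ
   per sample and channel, with a differential pathlength factor DPF(λ,
   age) from the standard five-term age/wavelength equation. Signals are
   then low-pass filtered (10th-order Butterworth, 0.1 Hz cut-off) and
   piecewise-linearly detrended.
2. **Trial screening** — 11-s post-onset trial windows are kept only when
   (i) HbO and HbR are negatively correlated, (ii) mean HbO exceeds mean
   HbR, and (iii) mean HbO is positive. Channels with ≥ 80 % rejected
   trials are dropped; subjects with no surviving channel are excluded.
   Retained trials are block-averaged per channel.
3. **Features** — eleven features of the averaged HbO response: mean HM,
   variance HV, excess kurtosis HK, skewness HS, activity-curve left and
   right slopes CSL/CSR, area CA, full width at half maximum CF, peak CP,
   activity start time CAS, and HDFT — magnitudes of discrete Fourier
   coefficients of the continuous HbO signal in the 0.01–0.1 Hz
   very-low/low-frequency oscillation band.
4. **Wrapper selection** — every one of the 2¹¹ − 1 = 2047 feature
   subsets is scored by repeated random-subsampling classification
   (stratified 70/30 splits, CART decision tree by default, LDA and
   polynomial-kernel SVM for comparison), reporting mean ± SD accuracy,
   sensitivity and specificity and a vertically averaged ROC/AUC.
5. **Spatio-temporal analysis** — the same protocol per feature on the
   16 per-channel values (missing where channels were pruned; the tree
   routes missing values to a learned child), plus population activity
   maps and hemispheric contrasts.

No recordings ship with the package. A first-class synthetic cohort
generator (`generate_cohort`) produces raw dual-wavelength recordings
with known ground truth — double-gamma hemodynamic responses with group-,
condition- and hemisphere-dependent effects, physiological oscillations,
drift, noise and motion-artifact trials — so that every stage is testable
end-to-end and planted effects can be recovered.

## Worked example

```r
library(fnirstbi)
cohort <- generate_cohort(n_healthy = 10, n_tbi = 10, seed = 42)
hemo   <- preprocess_cohort(cohort)
ft     <- feature_table(hemo)                 # High-complexity trials

score <- evaluate_subset(ft$temporal, ft$labels, c("CA", "HDFT", "CF"),
                         n_runs = 200, seed = 1, keep_scores = TRUE)
roc <- averaged_roc(score$run_scores, score$run_labels)

am <- activity_map(ft$spatiotemporal, "HV", rows = ft$labels == 0)
ct <- hemisphere_contrast(am)

cat("subjects analysed:", length(ft$labels), "(", ft$n_excluded, "excluded )\n")
for (m in names(score$metrics))
  cat(sprintf("%-11s %.2f +/- %.2f\n", m, score$metrics[[m]]["mean"],
              score$metrics[[m]]["sd"]))
cat(sprintf("AUC         %.2f\n", roc$auc))
cat(sprintf("healthy HV left-right contrast: %.3f\n", ct$difference))
```

Printed output of this exact script:

```
subjects analysed: 20 ( 0 excluded )
accuracy    0.76 +/- 0.14
sensitivity 0.81 +/- 0.25
specificity 0.70 +/- 0.20
AUC         0.76
healthy HV left-right contrast: 0.075
```

Meaning: on a 20-subject synthetic cohort with the default group effect
(healthy subjects respond more strongly, more narrowly and more
left-lateralized to the high-complexity task), the feature subset
{CA, HDFT, CF} classifies held-out subjects correctly in 76 % of 200
random 70/30 splits; TBI subjects are detected slightly more reliably
(sensitivity 0.81) than healthy ones (specificity 0.70). The positive
left-minus-right HV contrast reflects the planted lateralization of the
healthy response. `wrapper_search()` runs the full 2047-subset ranking;
`classify_spatiotemporal()` and `activity_map()` produce the per-channel
results.

## Command-line tools

Thin wrappers live in `inst/cli/` (after installation, under
`system.file("cli", package = "fnirstbi")`):

```sh
Rscript inst/cli/synth-cohort.R   --n-healthy 31 --n-tbi 30 --seed 1 --out cohort
Rscript inst/cli/preprocess.R     --in cohort/H01.csv --out hemo
Rscript inst/cli/trialqc.R        --in hemo --condition HighComplexity --out qc
Rscript inst/cli/features.R       --in hemo --mode both --out feat
Rscript inst/cli/wrapper-search.R --features feat/features_temporal.csv --out ws
Rscript inst/cli/spatial.R        --features feat/features_spatiotemporal.csv --out sp
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and
its assumptions, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, and the numerical
conventions and design choices.
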