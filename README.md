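# bspmaf

Spatiotemporal analysis of body-surface potential mapping (BSPM) signals in
persistent atrial fibrillation (persAF), for biomedical signal-processing
researchers and cardiac electrophysiology groups working with
multi-electrode vest recordings.

A 252-lead vest samples the cardiac electrical field far more densely than a
12-lead ECG. After the ventricular waveforms (QRST complexes) are cancelled,
the remaining atrial fibrillatory activity can be summarized by indices that
quantify how *spatiotemporally stable* the AF pattern is — a property that
relates to how treatable the arrhythmia is by catheter ablation. This
package implements that entire workflow:

* **Preprocessing** — bad-lead interpolation, zero-phase 1–30 Hz band-pass,
  Pan–Tompkins-style R-peak detection, QRST delineation and shape
  clustering, spatiotemporal (single-beat, multi-lead) template cancellation,
  z-normalization with a 10th-order 30 Hz low-pass.
* **Spectral analysis** — Welch power spectra (2-s Hamming windows, 50%
  overlap, 4096-point FFT) and per-lead dominant-frequency (DF) maps over
  the 3–12 Hz fibrillatory band.
* **Reconstruction** — least-squares reconstruction of all 252 leads from an
  electrode subset via the Moore–Penrose pseudoinverse (`A = S⁺X`), greedy
  sequential electrode selection (SEQ_k), fixed ECG-analogue subsets
  (ECG_8, ECG_11), and optimal rank-k PCA reconstruction
  (`X_k = U_k Σ_k V_kᵀ`, the Eckart–Young lower bound).
* **Indices** — for windows i = 2..W of a 1-min segment, with subset and
  mixing anchored on window 1:

      ER_NRMSE(i) = ‖Xⁱ − X̂ⁱ‖_F / ‖Xⁱ − X_kⁱ‖_F        (always ≥ 1)
      ER_ABSE(i)  = Σ_l |DF(Xⁱ) − DF(X̂ⁱ)| / Σ_l |DF(Xⁱ) − DF(X_kⁱ)|

  averaged over windows, plus the non-dipolar component index (NDI), the
  variance fraction beyond the first three principal components per window.
* **Evaluation** — group-wise (patient-level) stratified cross-validation,
  Lilliefors-gated ANOVA / Wilcoxon fold statistics, univariate logistic
  regression with ROC/AUC and Youden-threshold sensitivity/specificity.
* **Synthetic data** — a seeded generator of AF-like 252-lead recordings
  (harmonic atrial sources with a spatial DF gradient, QRST trains at
  irregular RR intervals, baseline wander, noise) with an *organized*
  (stable mixing) and a *disorganized* (per-window mixing drift + DF
  jitter) regime, so every stage is testable without clinical data.

## Worked example

Generate one organized and one disorganized synthetic 1-min atrial segment
(252 leads, 1 kHz) and compute the indices for a greedy 8-electrode subset
and the standard-ECG-analogue subset:

```r
library(bspmaf)

segO <- generateAASegment(synthConfig(regime = "organized",    seed = 42))
segD <- generateAASegment(synthConfig(regime = "disorganized", seed = 42))

cfg <- indexConfig(subsetKinds = c("SEQ8", "ECG8"))
tab <- rbind(
  computeAllIndices(segO, cfg, patientId = "demo", segmentId = "organized",
                    computeAbse = FALSE),
  computeAllIndices(segD, cfg, patientId = "demo", segmentId = "disorganized",
                    computeAbse = FALSE))
print(tab[, c("segment_id", "subset_kind", "er_nrmse", "ndi")], digits = 4)
```

```
    segment_id subset_kind er_nrmse     ndi
1    organized        SEQ8    1.371 0.07849
2    organized        ECG8    3.812 0.07849
3 disorganized        SEQ8    5.872 0.15005
4 disorganized        ECG8    9.173 0.15005
```

Read-out: `er_nrmse` is the ratio of the anchored subset-reconstruction
error to the same-rank PCA optimum, so 1.37 for the organized segment with a
data-driven SEQ_8 subset means the first window's electrode choice stays
near-optimal across the whole minute — temporally stable AF. The
disorganized segment, whose source-to-surface mixing drifts at every 5-s
window, scores 5.87: the anchored mixing goes stale. The fixed ECG-analogue
subset is worse than the data-driven subset in both regimes (3.81 and 9.17),
and the NDI (subset-independent, hence identical across rows of a segment)
is roughly twice as large for the disorganized segment.

A full synthetic cohort with regime-linked outcomes and cross-validated
classification:

```r
tab   <- simulateCohortIndices(nPatients = 11, segmentsPerPatient = 7, seed = 1)
folds <- groupwiseFolds(tab, nFolds = 3, testFrac = 0.2, seed = 1)
univariateRoc(tab, folds, valueCol = "er_nrmse")
```

A thin command-line front end is installed as `exec/bspmaf`
(`bspmaf synth | preprocess | dfmap | reconstruct | indices | evaluate | run`).

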