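---
title: "Spatiotemporal BSPM indices for persistent atrial fibrillation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal BSPM indices for persistent atrial fibrillation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspmaf)
```

## The problem

Body-surface potential mapping (BSPM) records the cardiac electrical field
with a dense electrode vest — here 252 unipolar leads at 1 kHz — rather than
the 12 leads of a standard ECG. In persistent atrial fibrillation (persAF),
the atrial component of the surface signal (the fibrillatory *f*-waves,
quasi-periodic oscillations at roughly 4–9 Hz) carries information about how
organized the underlying atrial activation is, and more organized AF tends to
respond better to catheter ablation. The question this package addresses is
how to turn a 1-minute, 252-lead atrial-activity recording into a small
number of indices that (a) quantify the spatiotemporal stability of the AF
pattern and (b) can be tested as predictors of ablation outcome (sinus
rhythm maintained, SR, versus arrhythmia recurrence, AR).

## The model

Let $X \in \mathbb{R}^{m \times n}$ be an atrial-activity segment ($m$
samples, $n = 252$ leads). Two reconstruction families bound each other:

* **Electrode-subset reconstruction.** For a subset matrix
  $S \in \mathbb{R}^{m \times k}$ of $k$ lead signals, the least-squares
  mixing is $A = S^{+} X$ (Moore–Penrose pseudoinverse), with reconstruction
  $\hat X = S A$. `pinvFit()` treats singular values below
  $10^{-10}\sigma_{\max}$ as zero and flags rank deficiency.
* **Rank-$k$ PCA reconstruction.** $X_k = U_k \Sigma_k V_k^{\mathsf T}$ from
  the truncated SVD. By the Eckart–Young theorem this is the best possible
  rank-$k$ approximation in the Frobenius norm, so it lower-bounds every
  $k$-electrode reconstruction; the package verifies this bound continually
  in its tests.

Subsets are chosen three ways: greedily from the data (`sequentialSelect()`,
adding at each step the electrode that most reduces the Frobenius error —
implemented by incremental orthogonalization, which is algebraically
identical to refitting the pseudoinverse and is asserted to be so in the
tests), or fixed at ECG-analogue positions (`ECG8`: precordial V1–V6
analogues plus two limb-equivalent leads; `ECG11`: `ECG8` plus three
posterior leads in the V6 plane).

Two error measures compare $X$ with $\hat X$: the normalized
root-mean-square error $\mathrm{NRMSE} = \|X - \hat X\|_F / \|X\|_F$ and the
dominant-frequency error $\mathrm{ABSE}$, the mean over leads of the
absolute difference between the Welch-spectrum dominant frequencies (DF) of
the original and reconstructed lead signals.

## The segment-level indices

A 1-min segment is cut into twelve non-overlapping 5-s windows (the tail
shorter than a window is dropped). On the **first window only**, the subset
is selected (for SEQ kinds) and the mixing $A^1$ fitted. Each later window
$X^i$ is then reconstructed with its own subset samples but the *anchored*
mixing, $\hat X^i = S_k^i A^1$, and compared with that window's own optimal
rank-$k$ PCA reconstruction:

$$\mathrm{ER}_{\mathrm{NRMSE}}^i =
  \frac{\|X^i - \hat X^i\|_F}{\|X^i - X_k^i\|_F} \ \ge\ 1, \qquad
\mathrm{ER}_{\mathrm{ABSE}}^i =
  \frac{\sum_l |\mathrm{DF}(X^i_{:,l}) - \mathrm{DF}(\hat X^i_{:,l})|}
       {\sum_l |\mathrm{DF}(X^i_{:,l}) - \mathrm{DF}(X^i_{k,:,l})|}.$$

Both are averaged over windows $2..W$ for one value per segment. The logic:
if the AF pattern is temporally stable, the first window's electrode choice
and mixing stay near-optimal, and the ratio stays close to 1; if the
source-to-surface pattern drifts, the anchored reconstruction degrades while
the per-window PCA denominator does not, and the ratio grows. The
**non-dipolar component index (NDI)** complements them: per window, the
fraction of variance not captured by the first three principal components of
the column-centered window, averaged over all windows — a subset-free
spatial-complexity measure in $[0, 1]$.

Numerical policies worth stating explicitly:

* The ER_NRMSE denominator is computed from the eigenvalues of
  $X^{\mathsf T}X$ (cheap for $m \gg n$); windows with a denominator below
  $10^{-12}$ are excluded and flagged.
* For ER_ABSE, leads with an undefined DF in any of the three matrices are
  excluded pairwise; a window with zero denominator scores 1 if its
  numerator is also zero and is excluded (and counted) otherwise. These
  degenerate cases cannot be resolved from the ratio definition itself, so
  the package makes the policy explicit and reports exclusions.
* NDI centers window columns before the SVD because it is a *variance*
  decomposition; the reconstruction indices use the uncentered SVD because
  they reconstruct the signal itself.
* Ties in the greedy selection and in DF peak picking break toward the
  lowest index / lowest frequency, for cross-platform determinism.

### In-sample optimism of the anchor window

Because the subset is both selected and fitted on window 1, the anchor
window's own reconstruction error is biased low relative to later windows
(classical training-set optimism). Two consequences are documented rather
than hidden: (i) window-1 error sits below the out-of-sample windows even on
perfectly stationary data (out-of-sample windows agree with each other to a
few percent); (ii) a per-window-refit variant of ER_NRMSE (selection and
fitting repeated in every window) is *always* below the anchored index, by
roughly 10% on stationary data at canonical scale and by several-fold under
mixing drift. The anchored-minus-refit gap is itself the temporal-stability
signal the index is designed to carry. Both modes are available
(`subsetErrorProfile(mode = "anchored" | "perwindow")`).

## Preprocessing chain

Raw vest recordings are dominated by ventricular activity (QRST complexes,
roughly eight times the atrial amplitude), baseline wander and broadband
noise. `preprocessRecording()` chains:

1. **Bad-lead repair** (`interpolateBadLeads()`): each flagged lead is
   replaced by the inverse-distance-weighted average of its K = 4 nearest
   good leads on the vest grid; an error is raised if more than half the
   leads are bad.
2. **Band-pass 1–30 Hz** (`bandpassRecording()`): zero-phase
   (forward–backward) Butterworth, implemented as a high-pass/low-pass
   cascade because a direct band-pass with a 0.002 normalized lower corner
   is numerically fragile. Zero-phase filtering is used everywhere so that
   peak shapes and template alignment are not biased by phase distortion.
3. **R-peak detection** (`detectRPeaks()`): Pan–Tompkins-style energy
   detection (differentiate, square, 150-ms integration) on the highest-RMS
   lead, 200-ms refractory period, peak refinement within ±80 ms.
4. **Delineation and clustering** (`delineateAndCluster()`): a fixed window
   (−80 to +400 ms) around each R-peak; beats clustered by correlation
   distance of their concatenated multi-lead shapes (hierarchical, complete
   linkage, cut at 2 clusters by default). Clusters with fewer than 3 beats
   are merged into their nearest cluster, and clusters whose ensemble
   templates correlate above 0.9 are collapsed, with the correlation
   computed on the high-amplitude samples of the pooled template (the
   ventricular-dominated portion): with a single true beat morphology,
   forcing two ensembles splits beats by their incidental atrial-activity
   phase, and each ensemble average then retains coherent atrial signal
   that the cancellation step would wrongly subtract — and that retained
   signal would itself depress a naive whole-template correlation below
   the merge threshold. Genuinely distinct morphologies (ectopy, polarity
   flips) differ precisely in the high-amplitude portion, so they are
   preserved.
5. **Spatiotemporal QRST cancellation** (`cancelQRST()`): per beat, the
   cluster template is aligned by an integer shift search (±20 ms) and
   fitted by a per-lead scalar scale (optionally, a rank-$p$ template basis
   for a low-order spatial transform), then subtracted; windows are trimmed
   at the next beat's onset so subtractions never overlap.
6. **Finalization** (`finalizeSegment()`): per-lead z-normalization, a
   zero-phase order-10 Butterworth low-pass at 30 Hz (an order-5 filter
   applied forward and backward) to remove subtraction discontinuities, and
   a re-standardization so every lead ends with exactly zero mean and unit
   variance. The final filter is not exactly idempotent: the f-wave third
   harmonic (~21 Hz) sits close to the 30 Hz cutoff, so a repeated pass
   changes about 2% RMS — an inherent property of repeated passband
   shaping, not an implementation artifact.

## The synthetic generator

No public clinical BSPM recordings accompany this method, so the package
includes a first-class, seeded generator (`synthConfig()`,
`generateFWaves()`, `generateRecording()`, `generateAASegment()`) that
emulates the signal properties the pipeline must handle. Its defaults *are*
the study conditions: 252 leads, 1 kHz, 60-s segments, 5-s analysis windows.

* **Atrial sources.** Four sources, each a harmonic series (fundamental,
  2nd and 3rd harmonics at amplitudes 1, 1/2, 1/4) with slow sinusoidal
  phase modulation (0.1 Hz, 0.3 rad). Source fundamentals span the target
  DF field (default: a smooth 5 to 7 Hz spatial gradient across the vest).
* **Mixing.** A frequency-proximity mixing matrix (Gaussian kernel,
  0.35 Hz bandwidth, lead columns normalized to 0.9) maps sources to leads,
  so each lead is dominated by the source nearest its target DF — giving a
  spatially smooth DF map. A weak per-lead sinusoid at the target DF
  (amplitude 0.08) adds per-lead spectral texture while keeping the
  organized regime effectively low-rank (99% of energy within
  `nSources + 1` dimensions). The generator reports as its DF ground truth
  the Welch DF of the clean f-wave matrix itself, which is the quantity a
  DF-recovery test can honestly be scored against.
* **Two regimes.** *Organized*: constant mixing, fixed fundamentals.
  *Disorganized*: at every 5-s window boundary the mixing takes an
  independent random step of 30% relative magnitude (then re-normalized)
  and the fundamentals are jittered by up to ±0.5 Hz, phase-continuously.
  Aligning the drift to the analysis windows makes the instability the ER
  indices are designed to detect explicit and controllable.
* **Ventricular activity and nuisance.** An analytic QRST template (three
  narrow Gaussians for Q/R/S plus a wide T-wave Gaussian, ~400 ms total) is
  placed at log-normal RR intervals (mean 0.7 s, CV 0.25 — irregular and
  strictly positive, as AF RR series are), scaled to 8× the atrial
  amplitude with a smooth random spatial pattern and 5% per-beat amplitude
  jitter; plus 0.3-Hz sinusoidal baseline wander (0.2 relative amplitude)
  and white noise (0.1 relative).

What the generator does *not* emulate — and hence what passing tests do not
show about clinical data: realistic torso volume-conduction geometry,
electrode-contact artifacts and lead dropout dynamics, ectopic-beat
morphologies, respiration-modulated wander, or the continuum of AF
organization between the two regimes. The regime dichotomy is a
parameter-recovery construction: it demonstrates that the indices detect the
kind of temporal instability they were designed for, not that clinical AUCs
will match.

## Spectral estimation

`welchPsd()` implements the Welch periodogram with 2-s Hamming windows, 50%
overlap and a 4096-point FFT (bin width ≈ 0.244 Hz at 1 kHz), one-sided
density scaling (checked against Parseval in the tests). The DF is the
highest in-band peak, with the search band set to 3–12 Hz — the canonical
fibrillatory band; the band is a configurable choice, not a claim. Flat
in-band spectra yield an undefined (NA) DF that propagates explicitly.

## Evaluation protocol

`groupwiseFolds()` builds three independent patient-level 80/20 splits,
stratified by outcome, so segments of one patient never straddle train and
test — the "3-fold CV with 20% left out" wording of the protocol is
interpreted as three repeated group-stratified splits rather than a
partition (a literal 3-fold partition would hold out 33%, contradicting the
80/20 statement). `foldSignificance()` applies, per fold on the held-in 80%,
a Lilliefors normality check per class (α = 0.05) and then one-way ANOVA
(both normal) or the Wilcoxon rank-sum test, reporting the mean p over
folds. `univariateRoc()` fits an unpenalized univariate logistic model on
the train-standardized index, scores test segments, reports AUC mean ± sd
over folds, and evaluates sensitivity/specificity (AR positive) at the
Youden-optimal threshold of the fold-pooled ROC; per-fold values at the same
threshold are also reported because the pooled-versus-per-fold convention is
ambiguous in general. Note that a trained univariate classifier is
sign-adaptive: negating the index flips the fitted slope and leaves the AUC
unchanged.

## Problem sizes used in the validation runs

The package's own validation (test suite and `scripts/acceptance.R`) uses:
100 random 60×20 matrices for the Eckart–Young and PCA-error identities; 100
random 20×6 matrices for the exhaustive greedy oracle; one canonical 252-lead
60-s recording for cancellation efficacy; 20 + 20 canonical segments for the
regime-separation property; an 11-patient × 7-segment synthetic cohort (6
AR / 5 SR, regime linked to outcome) for the classification protocol, with a
20-permutation label null; and a reduced 6-patient × 2-segment, 36-lead
pipeline run (twice) for bitwise determinism. Unit tests use
smaller fixtures (typically 36 leads, 15 s) of the same generator.

## Known limitations

* The vest geometry is synthetic (two 9×14 panels); ECG-analogue subset
  membership is a consistent, documented mapping, not the manufacturer's.
* WFDB and proprietary vendor formats are not read; recordings enter as
  delimited-text or flat-binary matrices with a JSON sidecar.
* The ER_ABSE denominator can legitimately vanish (PCA reconstruction
  DF-perfect on every lead); the exclude-or-one policy keeps the index
  defined but makes its tail behavior policy-dependent.
* Lead quality is an input (per-lead flags), not detected automatically;
  the clinical practice it models used visual inspection.
* The synthetic cohort links outcome to regime deterministically; clinical
  outcome prediction is far noisier, and the protocol here validates the
  machinery, not a clinical effect size.
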