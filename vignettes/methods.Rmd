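---
title: "Hybrid EEG-fNIRS markers of depression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid EEG-fNIRS markers of depression: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

neurofuse reconstructs a resting-state analysis that discriminates major
depressive disorder (MDD) patients from healthy controls using two
simultaneously recorded modalities: 28-channel scalp EEG (500 Hz) and
8-channel forehead fNIRS oxygenated-haemoglobin concentration change
(HbO~2~, 10 Hz). This vignette explains the models behind each stage, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the design decisions taken where the methodology was
genuinely open.

## The analysis chain

### EEG preprocessing

T7 and T8 are removed (muscle contamination), leaving 26 analysis channels.
The chain is: 50 Hz notch, 0.5-30 Hz band-pass, discard of the first 10 s,
re-referencing to the 26-channel average, segmentation into consecutive
non-overlapping 40-s epochs (20 000 samples each), automatic rejection of
any epoch containing a sample with |x| > 100 uV (strict inequality), and
retention of the first four surviving epochs.

Filter realizations are not dictated by the methodology we reproduce, so we
chose standard EEG practice and made the choices testable: the notch is a
second-order IIR biquad with quality factor 35; band filters are Butterworth
band-passes with a 4th-order transfer function; every filter runs
forward-backward with steady-state initial conditions and odd-reflection
padding, so filtering is zero-phase (a band-limited pulse's peak moves by at
most one sample — this is asserted in the tests). The +/-100 uV rule is
applied after filtering and re-referencing; the original description leaves
this order open, and our choice is recorded here rather than inferred.
Manual inspection steps are replaced by the automatic rule alone, for
reproducibility.

### Phase-locking networks

Band-limited signals (delta 0.5-4, theta 4-8, alpha 8-13 Hz) yield
instantaneous phases via the analytic signal, and each channel pair's
phase-locking value over an epoch of N samples is

$$\mathrm{PLV} = \Big| \tfrac{1}{N} \sum_{t=1}^{N}
  e^{\,i(\psi_x(t) - \psi_y(t))} \Big|,$$

computed over the whole 40-s epoch (N = 20 000; no sub-windowing) and
averaged across the four epochs into one 26 x 26 matrix per band.

For the cohort-scale pipeline the band filtering and Hilbert transform are
fused into a single FFT round trip per epoch: the squared magnitude response
of the band's Butterworth filter (exactly the zero-phase forward-backward
response) is applied in the frequency domain together with the one-sided
analytic-signal weighting. Interior samples match the time-domain path;
only edge transients differ, perturbing epoch-averaged PLV by well under
0.01 (asserted in the tests). The time-domain path remains available
(`band_method = "filtfilt"` or `extract_band()` + `plv_matrix()`).

Proportional thresholding at t keeps the strongest (1 - t) fraction of the
325 upper-triangle connections as binary edges; the edge target is
round-half-up of (1 - t) x 325, with ties broken deterministically by (row,
column) order. Six binary-network properties are computed with the standard
binary undirected definitions: clustering coefficient C, characteristic
path length L (mean finite shortest-path length; disconnected pairs are
excluded from L and contribute zero inverse distance to global efficiency
GE), local efficiency LE, transitivity T, and modularity M. Modularity is
exact for graphs of at most 8 nodes (enumeration of all set partitions,
tested against an independent enumeration oracle) and, beyond that, the
best Newman Q over 10 Louvain runs with internally seeded vertex
permutations, which makes M deterministic. Each metric is evaluated on the 31-point threshold
grid 0.20, 0.21, ..., 0.50 and summarized by its curve's area under the
curve (composite trapezoid), giving 6 metrics x 3 bands = 18 network
features per subject.

### Spectral asymmetry

Welch spectra use Hann-windowed 8.192-s segments (4096 samples, a power of
two at 500 Hz) with 50% overlap, averaged across segments and epochs.
Relative band power is the band's density sum divided by the total over
0.5-30 Hz; band sums use half-open intervals [f1, f2) so the 4 and 8 Hz
boundary bins belong to exactly one band. For each of the 11 symmetric
electrode pairs (F4-F3, F8-F7, FC2-FC1, FC6-FC5, C4-C3, CP2-CP1, CP6-CP5,
P4-P3, P8-P7, PO4-PO3, O2-O1) the asymmetry score is
(R - L)/(R + L) of the right and left relative powers: 33 features.

### fNIRS features

HbO~2~ preprocessing: zero-phase second-order Butterworth band-pass at
0.01-0.1 Hz, removal of a third-order least-squares polynomial trend,
wavelet denoising, discard of the first 30 s, and retention of a 3-min
window (1800 samples). The wavelet step is a Daubechies-4 (8-tap)
orthonormal decimated transform, 5 levels, with a soft universal threshold
(sigma estimated from the finest detail level by MAD/0.6745, threshold
sigma * sqrt(2 log N) applied to all detail levels); family and depth are
not dictated by the source methodology, so this common fNIRS choice is
exposed here as the package's own.

Sample entropy uses embedding dimension m = 2, delay tau = 2, tolerance
r = 0.2 SD of the preprocessed series, with the match-frequency
denominators implemented exactly as the source prints them
(`C_i^m = B_i / (N - (m+1)tau)`, averaged over the N - m tau templates).
This differs slightly from the classical Richman-Moorman convention, which
is available as `classical = TRUE` for cross-checks; the discrepancy is
surfaced rather than silently harmonized. Per-channel entropies give 8
features. ROI connectivity averages channel pairs (roi1 = ch1+ch3, roi2 =
ch2+ch4, roi3 = ch5+ch7, roi4 = ch6+ch8), Fisher-Z transforms the 6
pairwise Pearson correlations after clamping |r| <= 1 - 1e-7 (so perfect
correlation maps to z ~ 8.4 rather than infinity). The laterality index
anchors the side-averaged series at their minima and forms the normalized
right-minus-left difference, bounded in [-1, 1]. The hemisphere assignment
of ch1..ch8 is configuration, not inference: the default places ch1-ch4 on
the right forehead, and every laterality computation accepts an explicit
side map.

### Feature matrix, selection, classification

The 66 named features (18 + 33 + 8 + 6 + 1) carry modality prefixes
(`eeg_`, `fnirs_`). The clinical report this package reconstructs prints a
67-feature matrix while its described families enumerate to 66; the
remaining column cannot be identified from the text, so the package exposes
exactly the 66 enumerable features and records the discrepancy here as an
open question.

Normalization is min-max to [0, 1] per feature (Eq. `X' = (X - Xmin)/(Xmax
- Xmin)`), with the min/max fitted on a designated subject subset. Feature
selection is LASSO regression of the 0/1 group label with the penalty
chosen by 10-fold cross-validation on a 50-point log-spaced grid spanning
four decades down from the smallest all-zero penalty; features with
non-zero coefficients are kept, ranked by |coefficient|. Classification is
a linear SVM (C = 1) under leave-one-out cross-validation with backward
feature elimination: the ranked list is pruned by repeatedly dropping the
smallest-|coefficient| feature, each candidate subset scored by inner
10-fold CV accuracy, ties resolved toward the smaller subset.

A critical design decision: the literal order of operations in the source
(normalize and select once, then cross-validate) leaks the held-out
subject's values into scaling and selection. The package's default nests
normalization, selection and elimination inside every LOOCV fold, so the
held-out subject never influences its own fold's training (asserted in the
tests); `paper_mode = TRUE` reproduces the literal, leaky order for
comparison. Precision and recall take the patient group as the positive
class, and the ROC curve pools the signed distances to the hyperplane
across folds.

### Group statistics

Per feature: Shapiro-Wilk normality in each group at alpha = 0.05; if both
pass, a two-sided pooled-variance t-test, otherwise Mann-Whitney U; Cohen's
d (pooled SD, nA + nB - 2 denominator) is always reported. FDR correction
is Benjamini-Hochberg. For metric curves the correction families are: the
31 thresholds within each band x metric for curve comparisons, and the 6
metrics within each band for AUC comparisons (the methodology we reproduce
does not state its family definition; this one is recorded as
configuration). The demographic sex table uses Pearson's chi-squared
without continuity correction — the convention that reproduces the
published statistic (0.092) to three decimals.

## The synthetic cohort generator

No public recordings exist for this design, so the generator is a
first-class, tested module that emulates the statistical structure the
analysis assumes, with planted group differences calibrated once and then
frozen. The calibration targets were the clinical direction of every
effect and magnitudes large enough that, at 25 + 30 subjects, the group
comparisons and the EEG-versus-hybrid modality ordering are resolvable
across repeated simulated cohorts: the network features land at Cohen's d
around 1-1.6 and the haemodynamic features around 1.5-2.5 — deliberately at
or above the upper end of published effect sizes, because with 55 subjects
a LOOCV accuracy difference of a few percentage points (one to three
subjects) is otherwise lost in seed-to-seed noise.

EEG: each channel sums three band oscillations (carriers 2.25, 6, 10.5 Hz)
over a 1/f background (generated spectrally at a reduced rate and
upsampled, which keeps the exact 1/f shape across the whole 0.5-30 Hz
analysis band). Within a band, all channels share a driver phase and add
smooth stationary phase jitter with Gaussian autocorrelation (correlation
time 0.5 s) — chosen over an Ornstein-Uhlenbeck process because the OU
spectrum's heavy tails are clipped by the band-pass filters, which would
bias PLV above its analytic limit. Each channel's jitter mixes a spatially
shared field (latent processes at every electrode, mixed through a Gaussian
kernel over approximate 10-20 scalp coordinates) with an independent
component. Distant pairs therefore have phase-difference sd kappa and
expected PLV exp(-kappa^2/2) — the closed form that serves as the
generator's analytic oracle — while nearby channels synchronize more
strongly. Patients' delta and theta bands get both a larger shared fraction
(0.75 vs 0.50) and a wider kernel (0.75 vs 0.25 head radii), which makes
their thresholded networks geometric — locally clustered — and raises C and
LE (with T, L and M moving in sympathy, as such topology implies); alpha is
matched between groups. A right/left theta power ratio of 1.35 at FC2-FC1
plants the frontal asymmetry effect. Between-subject heterogeneity enters
through per-subject coupling fractions, kernel scales, power ratios and
noise amplitudes; a subject's coupling deviation is drawn once and shared
across bands — a subject who couples locally more than their group mean
does so in every band — so band-wise network features are correlated within
subject (as they are in real cohorts) while each band's group contrast
keeps its full size. This correlation is what keeps the EEG-only classifier
at realistic accuracy instead of stacking three nearly independent copies
of the same effect.

fNIRS: shared slow oscillations (0.02-0.08 Hz) with channel-specific phase
offsets, irregularity noise band-limited to the fast edge of the
haemodynamic band (0.07-0.25 Hz) with higher amplitude in patients, and a
small rightward amplitude imbalance in patients. The irregularity band was
chosen by measurement, not convention: broadband white noise cannot plant
an entropy contrast through this preprocessing chain, because the
0.01-0.1 Hz band-pass reduces it to a smooth in-band remnant whose main
effect is inflating the entropy tolerance r = 0.2 SD (sample entropy then
moves erratically, sometimes downward). Noise concentrated at the band's
fast edge survives preprocessing as a stable spectral tilt toward short
timescales, which raises sample entropy for every subject (verified by a
paired with/without-noise test) and mildly lowers measured ROI
correlations — a realistic consequence of noise on estimated connectivity,
not an independent knob.

What the generator does not emulate: volume conduction and source mixing,
non-stationarity across the recording, real artifact morphologies (the
artifact injector produces simple high-amplitude square pulses, off by
default), oxy/deoxy coupling, superficial haemodynamics, or any coupling
between the EEG and fNIRS signals of a subject beyond shared group
membership. Passing tests therefore demonstrate that the pipeline recovers
the kinds of effects it models, at realistic sizes, under controlled
conditions — not that it would behave identically on clinical recordings.

## Numerical choices and degenerate inputs

- PLV windows are whole epochs; matrices are symmetrized, clamped to
  [0, 1], unit diagonal.
- Edge-count rounding is half-up; PLV ties break by (row, column) order
  with a stable sort, so binarization is fully deterministic.
- An empty graph reports L as NA and M as 0; nodes of degree < 2 contribute
  0 to C and LE.
- Constant series: sample entropy is defined as 0 with a warning; a
  constant feature column min-max-normalizes to 0; a zero-variance group
  pair yields an NA effect size.
- All simulation randomness flows from the cohort seed through per-subject
  derived seeds (kept below 2^31), so identical configurations are
  bit-identical; the Louvain restarts use a fixed internal seed and restore
  the caller's RNG state.

## Problem sizes used by the tests and the acceptance script

The cohort-scale checks simulate 25 patients + 30 controls, mirroring the
study design. Simulated recordings are 190 s (EEG) and 240 s (fNIRS): the
analysis consumes exactly the first 10 + 4 x 40 s of EEG and 30 + 180 s of
fNIRS, so longer recordings only append samples the pipeline never reads;
the configuration default remains the full 6-min session. Planted-effect
recovery is evaluated over 10 seeds; unit tests use single subjects or
directly constructed epoch sets.

## Known limitations

- The 2-D scalp coordinates are schematic; the spatial kernel is a
  statistical device, not a forward model.
- At 26 nodes modularity is the best Q found by 10 seeded Louvain restarts,
  with no global-optimality guarantee (exact enumeration stops at 8 nodes).
- The spectral fast path assumes periodic epoch edges; users comparing
  against other implementations at tolerances below ~0.01 PLV should use
  the time-domain path.
- With 55 subjects, LOOCV accuracy has a standard error of roughly 5
  percentage points; seed-to-seed variation of that order is expected and
  is why recovery criteria are framed over repeated seeds.
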