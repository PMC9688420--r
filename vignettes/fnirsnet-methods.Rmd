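---
title: "Methods: graph-theoretical analysis of resting-state fNIRS connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretical analysis of resting-state fNIRS connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsnet)
```

## The analysis

`fnirsnet` implements a complete resting-state functional near-infrared
spectroscopy (rs-fNIRS) connectome analysis of the kind used to compare a
clinical group against controls and to predict symptom severity:

1. **Preprocessing** — raw three-wavelength light intensities are pruned
   (intensity range, positivity, SNR ≥ 2), converted to optical densities,
   motion-corrected (detection + cubic-spline subtraction), inverted
   through the modified Beer–Lambert law to HbO/HbR concentration changes,
   band-pass filtered to the spontaneous-activity band (0.01–0.08 Hz), and
   wavelet-denoised.
2. **Connectivity** — Pearson correlations between every pair of the 39
   channels' HbO series; negative coefficients are zeroed (their
   physiological meaning in rs-fNIRS is ambiguous), the rest Fisher
   z-transformed, and the matrix binarized at a sparsity threshold:
   exactly the top `round(s·N(N−1)/2)` z values become edges. At `s = 0.25`
   on 39 nodes that is 185 edges for every subject, so groups are compared
   on same-size networks; a 20–40% sweep (21 nested networks) probes
   robustness.
3. **Graph metrics** — clustering coefficient `Cp`, characteristic path
   length `Lp`, global and local efficiency, and their per-node versions
   (`Enod(i)`: mean inverse distance to all other nodes; `Eloc(i)`: global
   efficiency of the subgraph induced on a node's neighbors). `Cp` and
   `Lp` are normalized against degree-preserving Maslov–Sneppen rewired
   networks: `Gamma = Cp/⟨Cp_rand⟩`, `Lambda = Lp/⟨Lp_rand⟩`,
   `Sigma = Gamma/Lambda`; a small-world network has `Lambda ≈ 1`,
   `Gamma > 1`, `Sigma > 1`. Hubs are nodes whose group-averaged nodal
   efficiency exceeds the mean by at least one SD.
4. **Group statistics** — channel-wise pooled-variance t-tests with
   Benjamini–Hochberg FDR over the 39-channel family, pooled-SD Cohen's d,
   and a covariate-adjusted ANCOVA (Type II sums of squares) as a
   robustness check.
5. **Prediction** — ε-SVR (RBF kernel) predicting HAMD from a network
   metric under nested cross-validation: outer leave-one-out, inner
   10-fold grid search over (C, γ, ε) by mean squared error, features
   standardized inside each training fold only.

## The synthetic cohort generator

Subject-level rs-fNIRS data of this kind are not publicly distributable,
so the package ships a seeded generator that emulates the study
conditions and gives the pipeline a ground truth to be tested against:
34 patients and 30 controls, 10-minute recordings, 39 channels from 19
sources and 15 detectors (~3 cm separation), 50 Hz sampling at 730/808/850
nm, HAMD 22.55 ± 1.27 vs 6.66 ± 1.51.

**Signal model.** Channel signals are zero-mean Gaussian processes with a
block-structured correlation template: frontal/central blocks at r = 0.43,
the occipital block at r = 0.55, between-block r = 0.24. These levels were
calibrated once so the grand-mean off-diagonal correlation of simulated
cohorts lands near 0.31–0.32 with a between-subject SD near 0.06,
reproduced by scaling all off-diagonals by a per-subject coupling factor
`g ~ N(1, 0.18)` (clipped to [0.5, 1.4]; top-k binarization is invariant
to it, so it moves mean connectivity without touching topology). Spectra
are confined to 0.01–0.08 Hz by shaping frequency-domain Gaussian
coefficients with four zero-phase passes of the same order-3 Butterworth
design the preprocessing uses. One pass would be the literal
"filtered white noise" model, but its soft band edges make the pipeline's
own band-pass non-idempotent (the analytic ceiling on the noiseless
round-trip correlation is 0.985); four passes keep the same filter family
and raise the ceiling to 0.9988, which is what lets the round-trip
contract (> 0.99 per channel) be meaningful.

**Planted effect.** The clinical deficit is planted in covariance, not in
means: for each patient, the correlations *among* channel 36's template
neighbors (the other occipital channels, as determined by binarizing the
template itself at 25% sparsity) are scaled by
`λ = 1 − 0.29·d·(1 + 0.85·u)`, where `d` is the target standardized group
difference in `Eloc(36)` and `u ~ N(0,1)` is a per-subject severity. The
constants 0.29 (effect slope) and 0.85 (severity jitter) were calibrated
once, then frozen: at the default `d = 0.85` the realized deficit across
cohorts is 0.88 ± 0.25, with control `Eloc(36)` ≈ 0.77 ± 0.24 and patient
≈ 0.51 ± 0.33 — close to the group summaries the emulation targets.
Eigenvalue clipping (at 1e−8, followed by re-standardization) repairs the
rare slight indefiniteness introduced by the block edit.

**HAMD coupling.** Patient HAMD is the group baseline plus
`hamd_coupling · u` plus rounding noise, clipped at 0 and rounded to an
integer score. Because the printed HAMD SD (1.27) bounds how much of the
score can be severity-driven, and 600 s of band-limited signal bounds the
precision of the `Eloc(36)` estimate, the attainable true association
between HAMD and measured `Eloc(36)` has a ceiling near
`corr(HAMD, u) · corr(u, Eloc36) ≈ 0.91 × 0.51 ≈ 0.46` at the default
coupling of 1.15; setting the coupling to its maximum (1.27, the full
HAMD SD) yields a true association of ≈ 0.5, the regime used for the
prediction-recovery experiments.

**Optical forward model.** `generate_raw_intensity` embeds the
hemodynamics into intensities via the Napierian Beer–Lambert law
(extinction table converted from the standard compiled hemoglobin
spectra; path length = separation × DPF of 6), adds sinusoidal cardiac
(1.2 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) components with
per-channel random phases, white measurement noise, and exponentiates:
`I = i0·exp(−OD)`. Motion artifacts are injected as abrupt-onset events —
spikes with exponential recovery (≤ 1 s) and persistent baseline shifts —
at Poisson-random times, with amplitudes expressed in units of the
channel's log-intensity SD and every event logged for
sensitivity studies.

**What the generator does not emulate** — and hence what passing tests do
not establish about real recordings: optode–scalp coupling variation and
slow drifts, serially correlated (non-white) measurement noise,
physiological amplitude variation across cortex, HbR dynamics beyond a
fixed −0.3 proportionality, non-Gaussian heavy-tailed artifacts, and any
true anatomical geometry (the montage is a labeled index set, not a head
model).

## Numerical and design choices

- **Zero-phase band-pass.** The 0.01–0.08 Hz band sits at 4e−4–3.2e−3 of
  Nyquist at 50 Hz; the classic transfer-function Butterworth is
  numerically unusable there (measured passband gain errors of 4–70%),
  so the filter is designed as bilinear-transformed second-order sections
  and its squared (forward–backward) magnitude response is applied in the
  frequency domain. This is exact for the response and avoids the
  time-domain edge transients, whose ~100 s ring at the low band edge
  otherwise dominates 600 s recordings.
- **Motion detection.** A window is flagged when its peak-to-peak
  amplitude exceeds `amp_thresh` or the one-sample signal change exceeds
  `stdev_thresh` times the channel's robust (MAD) gradient SD; flags are
  dilated by `t_mask = 1 s`. Measuring the SD on the gradient makes a
  10-channel-SD abrupt artifact sit far above threshold even though
  `stdev_thresh = 30`, because band-limited signals have tiny gradients.
- **Spline correction** fits an interpolating cubic spline inside each
  flagged segment and subtracts it, which removes the segment's entire
  fluctuation; the segment is re-leveled to its left neighbor and all
  later samples are offset to keep the series continuous. In-band signal
  is essentially constant over artifact time scales, so this is a
  faithful, conservative repair; unflagged samples change only by those
  constant offsets.
- **Wavelet denoising** uses a hand-rolled periodized Daubechies-4 DWT
  (no wavelet package exists in the R dependency stack used here) with
  Tukey-fence shrinkage: detail coefficients beyond `α·IQR` of their
  scale are clipped to that bound. Scales with fewer than 128
  coefficients are left untouched — the robust spread estimate is
  unreliable there, and those coarse scales carry the band-limited signal
  itself rather than transients.
- **Binarization** keeps exactly the top-k edges (k rounded
  half-away-from-zero), with ties broken by ascending (row, column)
  index, so edge sets are deterministic and nested along the sparsity
  sweep.
- **Disconnected graphs.** `Lp` is the mean over reachable pairs with a
  `disconnected` flag (an infinite mean would poison `Lambda`);
  efficiencies let unreachable pairs contribute 0. Random references use
  the same conventions.
- **Nodal local efficiency** uses the neighbors-only induced subgraph.
  The variant that includes the index node is available behind
  `include_self = TRUE` but is not the default: it would score every
  degree-1 node 1.0, inverting the hub semantics.
- **Nested CV.** Inner folds are assigned by applying the seeded shuffle
  to training rows in canonical (outcome, features) order, making the
  partition a function of the training multiset — duplicated subjects are
  treated identically. Standardization parameters and hyperparameters are
  computed strictly inside each outer training fold.
- **Leave-one-out correlation bias.** Under a null (outcome unrelated to
  features), out-of-fold LOO predictions are *negatively* correlated with
  the outcome: the MSE-optimal null model predicts the training mean,
  which mechanically anti-correlates with the held-out value. Grids that
  admit flexible fits (small ε, larger γ) reduce but do not remove this
  bias (measured ≈ −0.15 for a flexible grid vs ≈ −0.21 for a smooth one
  at n = 34). This is a property of the protocol, not an implementation
  artifact; `permutation_pvalue` exists precisely so that observed
  correlations are referred to the protocol's own null distribution
  rather than to 0.

## Problem sizes used by the test suite

Replicate-heavy experiments generate the direct hemodynamic route at 2 Hz
rather than 50 Hz: for a 0.01–0.08 Hz band-limited Gaussian process of
fixed 600 s duration, any sampling rate above Nyquist carries the same
information, so correlation estimates — and everything downstream — are
statistically equivalent while generation is tenfold cheaper. Group
sizes, durations, the band, and planted effects are never reduced.
Random-network normalization uses 50 references in tests (1000 is the
study-scale default and remains the package default), and SVR grids in
tests are compact subsets of the default grids.

## Known limitations

- The wavelet step is an IQR-clipping stand-in for the family of
  published fNIRS wavelet-denoising methods; its tuning constant is
  exposed (`wavelet_alpha`) and its no-op limit (`Inf`) is exact.
- ANCOVA assumes homogeneous slopes (no group × covariate interaction
  terms are fitted).
- The probe layout is combinatorial, not geometric: channel positions,
  distances beyond the scalar separation, and anatomical labels other
  than the three region blocks are out of scope.
- With 39 channels and n = 34/30, single-channel effects near d = 0.85
  sit at the detection boundary once FDR-corrected; power analyses with
  this package should expect ~0.5–0.65 detection at that effect size,
  not the ~0.9 an uncorrected test would give.
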