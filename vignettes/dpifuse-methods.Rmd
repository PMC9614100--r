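---
title: "Evidence-theoretic fusion of EEG and detector streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-theoretic fusion of EEG and detector streams: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpifuse)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The fusion model

Two heterogeneous detectors watch the same trial stream: a human-vision
source (single-trial EEG decoded during rapid serial visual presentation)
and a computer-vision source (any external detector emitting per-trial
target posteriors). Evidence lives on the two-element frame
Θ = {target, non-target}; its power set adds the empty set (always mass 0)
and the composite {target, non-target}, which carries *uncertain* mass.

For each source φ a **detection-performance model** is fitted on validation
data: the empirical true-positive rate TPR(t) and true-negative rate TNR(t)
are computed on a grid of decision thresholds t (a trial is called target
when its posterior exceeds t), smoothed, and the operating threshold
`t_best = argmax_t [TPR(t) − FPR(t)]` — the Youden point — is selected.
Writing `g = TPR_smooth(t_best)` and `f = TNR_smooth(t_best)`, a trial with
posterior `p` receives the basic probability assignment

* m(target) = g · p,
* m(non-target) = f · (1 − p),
* m(uncertain) = 1 − m(target) − m(non-target).

Since g, f ∈ [0, 1] the triple is always a valid mass function. The
construction encodes the core idea: a source that detects targets
unreliably (small g) cannot place much mass on "target" no matter how
confident its posterior is, and the unassigned remainder is honest
uncertainty rather than forced class probability.

Per trial, the sources' masses are combined with Dempster's rule (normalised
intersection; the conflict mass K = m₁(t)m₂(nt) + m₁(nt)m₂(t) is discounted
by 1−K). The decision uses the pignistic transform **as printed in the
decision rule this package implements**: `P_pig(target) = m(target) +
m(uncertain)`, with the uncertain mass added in full to *both* singletons,
so the two pignistic values sum to 1 + m(uncertain). This is non-standard —
the classical transform splits the composite mass in half — but the decision
only thresholds `P_pig(target)`, for which the two versions are monotone
transformations of each other whenever masses are combined the same way; the
classical variant is available via `pignistic(m, split_uncertain = TRUE)`
for sensitivity analysis. Because fused pignistic scores live on their own
scale, the fused decision threshold is re-selected on the validation fold
(`select_fusion_threshold()`), independently of each source's `t_best`.

**Total conflict.** When 1 − K < 1e-12, Dempster's rule is singular.
`dempster_combine()` raises an explicit classed error carrying K; the
fusers never crash an evaluation over single trials — such trials are
counted, reported in the `fusion_result`, and scored by the renormalised
singleton ratio of the unnormalised combined masses (uncertainty zero).

## 2. The STHCP decoder

The human-vision stream is produced by a spatial–temporal hybrid decoder:

1. **Class covariances.** Per class, the average over trials of
   `Y Yᵀ / trace(Y Yᵀ)` where `Y` is a channels × samples epoch.
   Trace normalisation removes per-trial amplitude scale.
2. **CSP.** The generalised eigenproblem `U₊ w = λ U₋ w` is solved by
   whitening with the non-target covariance's Cholesky factor. Filters are
   kept *alternately from the two ends* of the eigenvalue spectrum
   (largest, smallest, 2nd largest, …): variance ratios far from 1 in either
   direction are discriminative, and this ordering makes a smaller filter
   bank a prefix of a larger one — which lets the hyperparameter search
   share one eigendecomposition. How the filters should be picked from the
   spectrum is genuinely open; alternating ends is our documented choice.
3. **Temporal PCA.** Per CSP-filtered channel, observations are trials and
   variables are time points; channel time courses are mean-centred across
   trials before the covariance, and the first K eigenvectors form that
   channel's projector. Per-channel (rather than shared) projectors follow
   from treating each virtual channel as its own time-domain subspace.
4. **Shrinkage LDA.** Gaussian shared-covariance discriminant with class
   priors from training prevalence; the target posterior is the logistic of
   the linear score. Trials enter as `n_filters × n_components` feature
   vectors.

The grid `n_filters ∈ [2,10] × n_components ∈ [1,10]` is searched by
validation AUC; ties break towards the smaller model (smaller filter count,
then smaller component count) for parsimony and determinism.

**Feature window.** The preprocessing description "segment 200–600 ms,
baseline 200 ms before the stimulus" is ambiguous: a 200–600 ms epoch cannot
contain a pre-stimulus baseline. We epoch −200 to +600 ms, baseline-correct
on −200–0 ms, and let the decoder extract features from a configurable
post-stimulus window (`feature_window_s`, default 0.2–0.6 s). This preserves
the stated baseline while honouring the stated analysis range; the
alternative reading (features from the whole epoch) is one argument away.

## 3. Preprocessing

Continuous recordings are notch-filtered at 50 Hz (RBJ biquad, quality
factor 30 — the `signal` package designs Butterworth but not notch filters,
so the standard biquad coefficients are computed directly) and band-passed
0.1–35 Hz, all zero-phase (forward–backward). The band-pass is a cascade of
a 2nd-order high-pass and a 4th-order low-pass: a single band-pass design
with a normalised low edge of ~1e-3 is numerically fragile under
forward–backward filtering, while the cascade is stable at any sampling
rate. Epochs too close to a record edge are dropped with a reported count;
baseline correction subtracts the per-trial, per-channel mean over the
baseline window and is idempotent.

## 4. What the synthetic generator emulates — and what it does not

`simulate_erp_epochs()` produces trials × channels × samples epochs with:

* exact prevalence: `round(n_trials × target_fraction)` targets (default
  25% of 1,500 trials);
* three Gaussian-bump ERP components on target trials — P1 (100–150 ms,
  positive, lateral-occipital weighting, default 3 µV), N2 (150–250 ms,
  negative, broad, 4 µV), P3 (350–400 ms, positive, central-parietal, 6 µV)
  — with per-trial amplitude jitter (multiplicative sd 0.25) and latency
  jitter (sd 15 ms). Each bump's Gaussian sd is a quarter of its window so
  the component roughly spans its window;
* background noise: 1/f (pink) noise of sd 9 µV, a 10 Hz oscillation of
  amplitude 3 µV with random phase, and white noise of sd 2 µV per sample;
* an `attention lapse` mechanism: a chosen fraction of target trials carry
  no ERP at all, emulating the failure mode the fusion is designed to
  absorb;
* a 64-channel extended 10–20 montage at 250 Hz, epochs −200 to +600 ms.

The amplitudes are from the component literature's order of magnitude; the
noise scale was chosen once so that the decoder's validation AUC on default
data sits in the 0.8–0.9 operating regime typical of single-trial RSVP
decoding (the acceptance suite verifies the regime). One global seed fans
out into independent sub-streams (trial order, noise, lapse selection,
jitter) so changing one knob does not reshuffle the others.

`simulate_detector_scores()` is a binormal score model: latent =
d′·label + Gaussian noise, mapped by a monotone logistic link to (0, 1);
population AUC = Φ(d′/√2), which the suite checks against the closed form.
The `dependence` parameter correlates two streams' latent noises
(conditionally on the label), and `lapse_fraction` blinds the source on a
random subset of targets.

Deliberately **not** modelled: volume conduction from dipolar sources, eye
and muscle artifacts, inter-subject variability, non-stationary drift,
continuous-recording structure, and realistic detector miscalibration
beyond the fixed logistic link. Passing tests therefore demonstrate the
pipeline's correctness and its qualitative behaviour (fusion gain, lapse
robustness, training-size response) under controlled conditions — not
performance on any real cohort.

## 5. Numerical choices

* **Threshold grid:** 101 evenly spaced points in [0, 1].
* **Smoother:** local linear regression (loess, span 0.25, direct surface)
  followed by isotonic projection (TPR non-increasing, TNR non-decreasing in
  the threshold) and clipping to [0, 1]; constants pass through unchanged.
  Deterministic and shape-respecting.
* **Ties in `t_best`:** smallest threshold wins (`which.max` takes the
  first maximum on the ascending grid).
* **Covariance shrinkage:** `(1−ε)S + ε·(trace(S)/p)·I`; ε = 1e-4 for CSP
  class covariances, 1e-3 for the LDA pooled covariance. Guarantees SPD
  without visibly moving well-conditioned solutions; both are arguments.
* **Eigenvector signs:** largest-magnitude entry made positive (CSP filters
  and PCA components), for cross-platform determinism.
* **Degenerate inputs:** single-class inputs, zero-energy trials,
  posteriors outside [0, 1], misaligned trial ids, empty grids, too-short
  threshold grids and shape mismatches all raise classed errors
  (`dpifuse_*_error`) naming the offending quantity; rates with zero
  denominators are refused rather than given 0/0 conventions.
* **Cross-validation:** stratified draw into four equal blocks (class
  counts per block within one trial of proportionality), cyclic successor
  rule for the validation block, up to 100 redraws if a block misses a
  class. Fold aggregates report the population standard deviation.

## 6. Baselines

**NBF** multiplies posteriors under conditional independence,
`posterior ∝ prior^(1−n) ∏ p_φ`, normalised against the non-target product,
with inputs clipped to [1e-6, 1−1e-6]. **DBF** builds masses from smoothed
validation precision/recall curves evaluated at the trial's own posterior
`s`: m(target) = precision(s), m(non-target) = 1 − recall(s), jointly
rescaled when their sum exceeds 1. Both are documented, deterministic
stand-ins for methods whose defining constructions live in prior work; they
are adequate for exercising the fusion machinery, not claimed to replicate
the originals.

**Known weakness of the DBF stand-in.** Because recall falls as the
threshold rises, `1 − recall(s)` assigns *large non-target mass to the most
confident detections*; on the synthetic pair its fused ranking is strongly
anti-diagnostic (AUC far below 0.5, as the experiment report shows). The
original belief-fusion method it stands in for moderates the non-target
term through a best-possible-detector construction that this package does
not reproduce. Comparisons against this baseline should therefore be read
as "DPI is well-behaved where the stand-in is not", nothing stronger.

## 7. Problem sizes used by the test and acceptance runs

The suite exercises the full pipeline at deliberately moderate sizes: unit
tests run on tens-to-hundreds of trials with reduced channel counts; the
qualitative acceptance properties use 1,500-trial score streams over 20
seeds (fusion gain), 10 seeds (lapse robustness), and 800–1,600-trial
64-channel EEG runs over 2 seeds with a 3 × 3 hyperparameter grid (decoder
regime, lapse degradation, training-size response). `scripts/acceptance.R`
runs the complete decode–model–fuse–evaluate pipeline once at 1,500 trials
with the full 9 × 10 grid. These sizes were chosen as the smallest at which
the checked effects dominate Monte-Carlo noise.

## 8. Limitations

* The pignistic transform is implemented as printed in the decision rule
  (uncertain mass added to both singletons); downstream consumers wanting a
  proper probability should use `split_uncertain = TRUE`.
* The DBF baseline is a stand-in with a known anti-diagnostic failure mode
  (section 6).
* The generator's scalp profiles are fixed weight vectors, not a forward
  model; CSP benefits from spatial structure but the spatial statistics of
  real EEG are richer.
* `run_experiment()` assumes both sources observed the same trials in the
  same order; it checks label agreement and trial alignment but cannot
  detect a silently permuted detector file whose labels happen to match.
* No statistical comparison across methods is performed (the per-fold sd is
  descriptive); cohort-level significance testing would need many
  independent subjects.
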