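---
title: "Detecting slow muscle-activation onsets from the entropy of the Hilbert marginal spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting slow muscle-activation onsets from the entropy of the Hilbert marginal spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgonset)
```

## The problem

Muscles dominated by slow-twitch fibers — the soleus during quiet walking is
the canonical example — activate gradually: the surface EMG amplitude rises
over hundreds of milliseconds to seconds, with no sharp boundary between
rest and contraction. Fixed amplitude thresholds and instantaneous-energy
detectors key on abrupt changes and therefore fire late, or not at all, on
such signals. What does change early and progressively during a slow
activation is the *distribution* of signal energy over frequency: quiescent
baseline recordings are spectrally diffuse (broadband instrumentation and
tissue noise), while muscle activity concentrates energy in the typical
sEMG band. This package detects onsets by tracking that spectral
redistribution rather than the amplitude itself.

## The detector

For a single-channel recording $x(t)$ sampled at $f_s$ Hz the full pipeline
(`detect(x, mode = "mse")`) is:

1. **Band-pass filtering.** A 5th-order Butterworth band-pass (20–450 Hz)
   applied forward and backward, so pass-band timing is exactly preserved
   (the two-pass application makes the effective order 10). Edges are
   handled by odd-reflection padding.
2. **Sliding windows.** Windows of 128 ms with 50% overlap; window $k$
   (1-based) starts at $t_0 + (k-1)s$ seconds, where $s$ is the step.
   Each window is z-scored (population standard deviation) before
   decomposition; this stabilizes numerics and has no effect on the
   entropy, which is scale-free.
3. **Empirical mode decomposition.** Each window is sifted into intrinsic
   mode functions $c_i(t)$ plus a residual, with the residual defined as
   the remainder so that $\sum_i c_i + r \equiv x$ holds to machine
   precision. At most 6 modes are extracted.
4. **Hilbert marginal spectrum.** Each IMF's analytic signal
   $z_i = c_i + \mathrm{j}\,\mathcal{H}\{c_i\}$ yields an instantaneous
   amplitude $A_i(t)$ and frequency $f_i(t)$; accumulating
   $A_i(t)\,\Delta t$ into equal-width frequency bins gives the marginal
   spectrum $h(\omega)$, a cumulative amplitude-per-frequency measure.
5. **Normalized spectral entropy.** With $p_i = h_i / \sum_k h_k$,
   $\mathrm{MSE} = -\sum_i p_i \ln p_i \,/\, \ln n \in [0, 1]$:
   1 for a spectrally diffuse window, 0 for a single-bin spectrum.
6. **Trend and steepest drop.** The per-window sequence
   $M = [\mathrm{MSE}_1, \dots, \mathrm{MSE}_K]$ is smoothed by a centered
   moving average (length 5 windows, truncated at the edges) into a trend
   $T$; the onset window is $k^\ast = \arg\min_k (T_{k+1} - T_k)$ —
   the steepest entropy *drop*, activation being a transition from diffuse
   to concentrated spectra — and the onset time is
   $t^\ast = t_0 + (k^\ast - 1)s$.

The detector involves no amplitude threshold anywhere: every decision
statistic is normalized, which is the core argument for it on low-amplitude
slow activations.

## Parameters that matter

| Key | Default | Units | Why |
|---|---|---|---|
| `filter.low_hz`, `filter.high_hz` | 20, 450 | Hz | Standard sEMG band; removes drift/motion artifact below and wideband noise above. |
| `window.length_ms` | 128 | ms | Short enough to localize the transition, long enough (192 samples at 1500 Hz) for a usable decomposition; stable over a 96–192 ms scan. |
| `window.overlap` | 0.5 | — | 64 ms effective time resolution at the default plan. |
| `emd.max_imfs` | 6 | — | Caps decomposition depth; deeper modes carry no EMG content at these window lengths. |
| `emd.sd_tol` | 0.2 | — | Cauchy sifting tolerance, the classical choice; sifting additionally continues until the candidate satisfies both parts of the IMF definition. |
| `hht.n_bins` | 45 | — | Equal-width bins over [0, 450] Hz, i.e. 10 Hz resolution matching the pass band. |
| `hht.edge_exclude` | 0.05 | — | Fraction of samples masked per window edge against Hilbert end effects. |
| `detector.smooth_len` | 5 | windows | ≈0.45 s of context at the default plan: suppresses entropy estimator noise at the cost of trend lag. |
| `detector.reject_delta` | 0 | entropy/step | Optional no-activation guard: reject when even the steepest drop is shallower than −δ. Off by default; the benchmark harness switches it on (δ = 0.02). |

## Numerical choices

* **Envelopes.** Natural cubic splines through the extrema, with the two
  extrema nearest each end mirrored outside the signal before fitting;
  fewer than four knots falls back to linear interpolation. Extrema are
  strict sign changes of the first difference; a plateau counts once, at
  its midpoint.
* **Sifting stop rule.** A candidate is accepted when the Cauchy criterion
  $\sum(h_{\mathrm{prev}} - h)^2 / \sum h_{\mathrm{prev}}^2 < 0.2$ holds
  *and* the candidate satisfies the IMF definition (extrema and
  zero-crossing counts differing by at most one, interior local-mean
  magnitude at most 10% of interior RMS), or after 100 iterations
  (flagged). An all-zero candidate returns immediately.
* **Instantaneous frequency.** Central differences of the unwrapped
  analytic phase; one-sided at the ends. Non-positive or super-Nyquist
  estimates are spline/Hilbert artifacts and are masked out rather than
  clamped, as are the first and last 5% of samples.
* **Binning.** Frequencies at or above the upper edge accumulate into the
  last bin; empty bins contribute exactly $0$ to the entropy (the
  $0 \ln 0$ limit), with no $\varepsilon$ plug-in.
* **Degenerate windows.** A near-constant window (population SD below a
  scale-aware guard) z-scores to zeros; a window with no usable spectrum
  inherits the previous window's entropy (1.0 for a failing first window).
* **Ties.** The earliest window wins the argmin — the conservative choice
  when early detection is the point.
* **Entropy endpoints.** Exactly-uniform spectra return exactly 1 (the
  maximum is attained symbolically, bypassing floating-point roundoff).

## Ablation modes

Three variants isolate the contribution of each module, selectable through
`detect(mode = ...)`:

* `energy-slope` replaces the entropy statistic with per-window mean
  squared amplitude. Activation *raises* energy while it *lowers* entropy,
  so this mode places the onset at the steepest rise of the max-normalized
  energy trend (applying the drop rule verbatim to energy would detect
  deactivations).
* `mse-only` removes the slope analysis: the onset is the global minimum
  of the smoothed entropy trend. Its rejection rule triggers when the
  trend's total excursion is below δ.
* `mse-nowindow` removes the sliding window: one EMD of the whole signal
  feeds a cumulative-to-$t$ marginal spectrum whose entropy is evaluated on
  the window plan's time grid, and the steepest drop of that unsmoothed
  sequence gives the onset. This is one defensible reading of "no sliding
  window"; a per-sample instantaneous entropy is not well defined for this
  statistic.

## Comparison detectors

Four standard baselines share the preprocessing stage: a relative amplitude
threshold (linear envelope = rectification + 2nd-order zero-phase 10 Hz
low-pass; onset at 30% of the envelope maximum), the Teager–Kaiser energy
operator ($\Psi(i) = x_i^2 - x_{i-1}x_{i+1}$, 50 ms smoothing, baseline
threshold $\mu_b + 8\sigma_b$ held for 2×50 ms), RMS windowing
($\mu_b + 3\sigma_b$ over the per-window RMS with a two-window persistence
rule), and wavelet detail energy (periodic db4 pyramid, 4 levels, same
persistence rule). The first 300 ms of the recording are assumed quiescent
and provide the baseline statistics. The threshold and entropy detectors
are scale-invariant by construction; the TKE/RMS/wavelet thresholds scale
with the signal, so their detections are scale-invariant too.

## The synthetic generator

`generate_emg()` produces $x(t) = b(t) + e(t)\,a(t)$: a unit-variance
baseline $b$ (Gaussian noise band-passed to 20–450 Hz, spectrally flat in
band, emulating instrumentation/tissue noise), an activation component $a$
scaled to $\sigma_a = 10^{\mathrm{SNR_{dB}}/20}$, and a smoothstep envelope
$e = 3u^2 - 2u^3$ rising from 0 to 1 over a known ramp $[t_{on},
t_{on}+\mathrm{rise}]$. The activation component is spectrally shaped with
the classical two-pole sEMG power-spectrum model (characteristic
frequencies 60 and 120 Hz) before band-limiting. This shaping is essential,
not cosmetic: with a spectrally identical activation, positives and
negatives are the same Gaussian process up to a time-varying scale factor,
and a scale-free detector cannot distinguish them *in principle*. A
`shape = "flat"` switch retains that null construction for sanity checks.
The baseline persists during activation, as in real recordings, so the
asymptotic measured SNR is $20\log_{10}\sqrt{1 + \sigma_a^2}$.

What the generator deliberately does **not** emulate: motor-unit action
potential trains and their firing statistics, gait-cycle periodicity,
electrode-motion artifacts, ECG crosstalk, or nonstationary baselines.
Passing the synthetic benchmark therefore demonstrates correct mechanics
and the intended qualitative response to gradual spectral redistribution —
not clinical-grade performance on real recordings.

```{r}
gen <- generate_emg(synth_spec(duration = 5, t_on = 2, rise = 0.4,
                               snr_db = 20, seed = 7))
detect(gen$signal, mode = "mse")
```

## Evaluation conventions

A detection within 0.2 s of the true onset is a true positive; on
no-activation recordings any detection is a false positive. RMSE is
computed over true positives; "detection advance" for method $A$ against a
reference $R$ is the mean of $t^\ast_R - t^\ast_A$ over signals both
detect, so the reference's own advance is 0 by construction (the relative
amplitude threshold is the default reference). Ground truth defaults to
the ramp *start* — the earliest physiologic activity — with a `truth_ref =
"mid"` option to re-reference to the ramp midpoint. Rates with zero
denominators are reported as missing, never as zero.

## Problem sizes

The test suite exercises the pipeline on signals of 0.1–6 s at 1500 Hz;
the benchmark used by the acceptance checks and `scripts/acceptance.R` is
50 recordings of 6 s (25 slow activations with rise 0.5–2.0 s at 10 dB
SNR, 25 negatives), chosen as the smallest set on which the rate estimates
are meaningful.

## Known limitations

* **Weak contrast at realistic SNR.** On the synthetic conditions above,
  the per-window entropy contrast between baseline (≈0.93) and fully
  active (≈0.84) segments is small relative to the entropy estimator's
  noise on 192-sample windows (SD ≈ 0.02–0.03, *larger* on the
  spectrally concentrated active plateau). The steepest-drop argmin is
  then a fragile statistic: in a sizeable minority of signals it lands on
  an active-plateau noise fluctuation instead of the ramp, producing a
  heavy tail of late detections. The acceptance script quantifies this
  honestly (`mse_median_abs_onset_error_s`,
  `mse_median_abs_error_vs_midramp_s`); the interested reader should run
  it rather than trust any single demonstration signal.
* **Mid-ramp bias by construction.** Every detector in the package —
  entropy-based or amplitude-based — responds once the activation
  component is an appreciable fraction of the mixture, i.e. partway up
  the ramp. Against a ramp-*start* ground truth all methods are
  systematically late by a rise-dependent amount; this is a property of
  the task, not of any one detector.
* **Rejection calibration.** The no-activation guard compares the
  steepest trend drop against δ in entropy-per-window-step units. At
  δ = 0.02 the guard is conservative on these synthetic signals (their
  genuine ramp slopes are ≈0.01–0.015 per step): specificity is high but
  many true activations are rejected. δ is exposed in configuration
  precisely because this trade-off is data-dependent.
* **Offline only.** The entropy sequence, smoothing and differencing are
  computed after the whole recording is available; no incremental update
  is provided.
* **Short-window EMD.** Decomposing each 192-sample window independently
  limits the resolvable low-frequency content and makes the deepest modes
  edge-dominated; the 5% edge mask mitigates but does not remove this.
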