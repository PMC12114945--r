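# emgonset

Onset detection for slowly activated muscle from single-channel surface
EMG (sEMG).

Slow-twitch muscles such as the soleus activate gradually: during walking
their surface EMG amplitude ramps up over hundreds of milliseconds with no
abrupt boundary, which defeats the classical onset detectors (fixed
amplitude thresholds, Teager–Kaiser energy, RMS windowing, wavelet
energy). What does change progressively during a slow activation is how
signal energy is *distributed* over frequency. `emgonset` implements a
detector that tracks this spectral redistribution through the normalized
Shannon entropy of the Hilbert marginal spectrum, together with the four
classical baselines, three ablation variants, a seeded synthetic
slow-activation generator with known ground truth, and an evaluation
harness.

## The statistic

Each 128 ms window (50% overlap, z-scored) is decomposed by empirical mode
decomposition into intrinsic mode functions $c_i(t)$; the Hilbert
transform gives each mode an instantaneous amplitude $A_i(t)$ and
frequency $f_i(t)$, and accumulating $A_i(t)\,\Delta t$ over time into
equal-width frequency bins yields the marginal spectrum
$h = [h_1, \dots, h_n]$ (45 bins over 0–450 Hz by default). With
$p_i = h_i / \sum_k h_k$, the marginal spectrum entropy of the window is

$$\mathrm{MSE} = -\frac{1}{\ln n}\sum_{i=1}^{n} p_i \ln p_i \in [0, 1],$$

near 1 for spectrally diffuse quiescent noise and lower once muscle
activity concentrates the spectrum. The per-window sequence is smoothed by
a centered moving average into a trend $T$, and the onset is placed at the
steepest drop:

$$k^\ast = \arg\min_k \, (T_{k+1} - T_k), \qquad
  t^\ast = t_0 + (k^\ast - 1)\,s,$$

with $s$ the window step in seconds. No amplitude threshold appears
anywhere in the decision path.

## Worked example

```r
library(emgonset)

# a 5 s surrogate recording: quiescent baseline, activation ramping
# up over 0.4 s starting at t = 2 s, 20 dB SNR, fixed seed
gen <- generate_emg(synth_spec(duration = 5, t_on = 2, rise = 0.4,
                               snr_db = 20, seed = 7))
gen$signal
#> <emg_signal> 7501 samples @ 1500 Hz, t0 = 0 s, duration = 5.0000 s

detect(gen$signal, mode = "mse")
#> <onset_result> method = mse: t* = 2.3040 s (window k* = 37)

detect_threshold(bandpass(gen$signal))
#> <onset_result> method = threshold: t* = 2.2067 s (window k* = 3311)
```

The entropy detector flags window 37 — the window where the smoothed
entropy trend falls fastest, i.e. where the spectrum concentrates most
rapidly — giving `t* = 2.304 s` against a true ramp start of 2.0 s
(detectors of every family respond partway up the ramp, once the
activation is an appreciable fraction of the mixture; here the 30%
amplitude threshold crosses at 2.207 s). For the relative amplitude
threshold detector `k*` is a sample index, not a window index.

A labelled benchmark across all detectors:

```r
ds  <- make_benchmark_set(50, rise_range = c(0.5, 2), snr_db = 10,
                          seed0 = 1000)
rep <- run_benchmark(ds)   # sensitivity/specificity/FNR/FPR/RMSE/advance
rep$metrics
```

There is also a thin command-line front end:

```sh
Rscript inst/cli/emg-onset.R simulate --seed 7 --rise-ms 400 --snr-db 20 --out demo.csv
Rscript inst/cli/emg-onset.R detect --input demo.csv --fs 1500 --method mse
Rscript inst/cli/emg-onset.R benchmark --n 50 --seed 1000 --out bench
```

See `vignettes/mse-onset-detection.Rmd` for the model, every tunable
parameter, the numerical choices, and the known limitations — including a
frank account of when the steepest-drop statistic is fragile.

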