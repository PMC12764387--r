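# cardiowave

Electrical stimulation during cardiac differentiation changes how
hiPSC-derived cardiomyocytes beat: how synchronously calcium transients
arrive across the tissue, how long each calcium cycle lasts, how fast
and how directionally calcium waves propagate, and how fast the
monolayer contracts and relaxes. `cardiowave` is an R package for the
computational side of such studies. It provides:

* a **digital twin of the stimulation signal generator** — biphasic,
  monophasic and alternating monophasic pulse trains; static schedules
  and linear multi-day ramps of frequency or pulse duration; ideal
  waveform rendering; and signal-fidelity measurement (cathodic,
  anodic and total pulse durations by mid-amplitude threshold
  crossing, with percent error against the programmed pulse);
* **seeded synthetic recordings with exact ground truth** — GCaMP-like
  calcium movies (synchronous fields, plane waves, and diverging/
  converging source–sink patterns built from a linear-rise /
  exponential-decay transient kernel), bare ROI trace sets with
  injected timing jitter, and phase-contrast-like beating-motion
  movies;
* the **optical analysis pipeline** — ΔF/F0 normalization
  (F0 = 10th percentile), peak detection, per-peak full width at half
  maximum, decay-constant fitting, the time-of-peak-arrival median
  absolute deviation (TPA-MAD) synchronicity statistic, Horn–Schunck
  optical flow with OFAMM-style preprocessing (3×3 spatial median,
  zero-phase <1 Hz temporal low-pass), circular statistics of wave
  direction, and contraction/relaxation velocimetry.

The quantities at the core are, per transient, the width
`FWHM = rise/2 + tau·ln 2` and the decay constant `tau` of
`A·exp(−t/tau)`; across regions, `TPA-MAD = median_beats(
median_i |t_i − median_i(t_i)| )` of peak-arrival times; and per frame
pair the Horn–Schunck field `(u, v)` minimizing
`(E_x u + E_y v + E_t)^2 + α^2 (|∇u|^2 + |∇v|^2)`, summarized by the
mean magnitude (µm/s) and the circular variance
`1 − |mean(exp(iθ))|` of the vector phase.

## Worked example

Build the ramped-frequency regimen (1→2 Hz over 10 days) and read off
its rates and daily schedule log:

```r
library(cardiowave)
sch <- build_schedule("ramped_frequency",
                      pulse_spec("biphasic", 4, 4, 1),
                      pulse_spec("biphasic", 4, 4, 2), duration_days = 10)
sch$rates$frequency_Hz_per_min
#> [1] 6.944444e-05
head(regimen_log(sch, step_minutes = 1440), 3)
#>   t_min frequency_Hz phase_duration_ms
#> 1     0          1.0                 4
#> 2  1440          1.1                 4
#> 3  2880          1.2                 4
```

The per-minute rate is the printed 6.94×10⁻⁵ Hz/min, i.e. 0.1 Hz/day.

Measure a synthetic plane wave (10 µm/s, 30° direction, 2 µm pixels,
20 frames/s) with the flow pipeline:

```r
g <- generate_wave_movie(h = 128, w = 128, pixel_size = 2, frame_rate = 20,
                         nframes = 120, pattern = "plane_wave", speed = 10,
                         direction = pi/6, noise_sd = 0.02, seed = 11)
flow_summary(compute_flow_sequence(preprocess_movie(g$movie)))
#> <flow_summary> mean |v| = 10.5 um/s, circular variance = 0.0592
#>   (mean dir 34.2 deg, n = 1754726)
```

Speed is recovered within 5%, direction within ~4°, and the low
circular variance flags unidirectional propagation (a matched `source`
movie gives ≈ 0.96).

Transient kinetics and synchronicity from a jittered 16-ROI trace set,
and contractility from a beating-motion movie:

```r
ts <- normalize_traces(generate_trace_set(n_rois = 16, n_beats = 8,
                                          jitter_sd_ms = 100,
                                          noise_sd = 0.02, seed = 7)$traces)
pk <- detect_peaks(ts, min_prominence_dff = 0.5)
m  <- transient_metrics(ts, pk)
tpa_mad(ts, pk)$tpa_mad_ms
#> [1] 50
median(m$fwhm_ms, na.rm = TRUE); median(m$tau_ms, na.rm = TRUE)
#> [1] 508.7343
#> [1] 390.3986

mo <- generate_motion_movie(h = 64, w = 64, nframes = 100,
                            beat_period_ms = 1000, peak_displacement_px = 3,
                            contraction_fraction = 0.45, seed = 5)
contraction_relaxation_metrics(velocity_trace(mo$movie))
#> <contractility_metrics> contraction 13.8 um/s, relaxation 11.4 um/s
#>   over 5 beats
```

The generating kernel had FWHM 499.5 ms and τ = 360 ms; the measured
medians sit within the sampling resolution of one 50 ms frame. The
TPA-MAD of 50 ms reflects the injected 100 ms jitter at frame
quantization, and the asymmetric beat (contraction over 45% of the
cycle) contracts faster than it relaxes.

`run_pipeline()` orchestrates all of this over a multi-condition
configuration (see `inst/extdata/demo_config.json` for a six-condition
layout mirroring a static-versus-ramped stimulation study) and writes
per-condition CSV/JSON artifacts plus a consolidated, seed-reproducible
report.

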