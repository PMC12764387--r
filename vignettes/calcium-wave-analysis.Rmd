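---
title: "Models and methods behind cardiowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiowave)
```

`cardiowave` packages the computational side of a stimulated
hiPSC-cardiomyocyte functional assay: a digital twin of a programmable
electrical-stimulation signal generator, seeded synthetic GCaMP and
phase-contrast recordings with exact ground truth, and the optical
analysis pipeline that turns such recordings into kinetics,
synchronicity, wave-directionality and contractility metrics. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic tests do and do not demonstrate about
real recordings.

## The stimulation regimen twin

A stimulation pulse is described by its shape (biphasic, monophasic, or
alternating monophasic), amplitude (V), per-phase duration (ms), and
repetition frequency (Hz). A biphasic pulse delivers a cathodic phase
(+V) immediately followed by an equal anodic phase (-V), so its net
charge is zero; alternating monophasic trains flip polarity every
period and are charge balanced over any even number of pulses.

"Pulse duration" in culture-stimulation protocols is ambiguous between
per-phase and total width. `cardiowave` interprets it as **per-phase**
duration — the fidelity convention of reporting cathodic, anodic and
total durations separately only makes sense per phase — and
`pulse_spec(..., total_duration = TRUE)` switches to the total-width
convention when needed.

Multi-day regimens are `regimen_schedule` objects: static, or linear
ramps of frequency or phase duration between two endpoint
specifications. Ramping 1 to 2 Hz over 10 days gives
$(2-1)/(10 \cdot 1440) \approx 6.94\times10^{-5}$ Hz/min (0.1 Hz/day);
ramping 4 to 8 ms gives 0.4 ms/day. `param_at()` evaluates the schedule
continuously in minutes; `regimen_log()` exports the per-step table a
stimulation device would log. The hardware envelope (2 ms–1 s phase
duration, up to 50 Hz) is enforced only when `device_limits = TRUE`, so
simulations may explore beyond it.

Waveform fidelity closes the loop: `sample_waveform()` renders the
ideal voltage trace (pulses laid out by sample index so that each phase
holds exactly the same number of samples — biphasic charge balance then
holds to machine precision), `measure_pulse()` reads phase durations
back by mid-amplitude threshold crossing with linear interpolation
between bracketing samples (the standard pulse-timing convention,
averaged over all pulses in the trace), and `fidelity_report()` turns
measured-versus-programmed durations into percent errors.

## The synthetic transient and its closed forms

All generators share one transient kernel: a linear rise to peak over
$t_r$ followed by exponential decay $e^{-t/\tau}$. Its full width at
half maximum is analytic,

$$\mathrm{FWHM} = \frac{t_r}{2} + \tau \ln 2,$$

because the half-maximum is crossed at $t_r/2$ on the way up and at
$t_r + \tau\ln 2$ on the way down. This gives every kinetics estimator
an exact oracle. The default kernel ($t_r$ = 500 ms, $\tau$ = 360 ms,
amplitude 1 ΔF/F0) matches the day-10 kinetics reported for
dynamically stimulated hiPSC-CM cultures (FWHM ≈ 500 ms, τ ≈ 360 ms)
and decays well inside the default 2 s beat period
($t_r + 3\tau < 2000$ ms), so consecutive beats overlap only weakly.

The default beat period of 2000 ms (0.5 Hz) sits at the low end of the
spontaneous beating range of these cultures (0.5–2 Hz). It was chosen
once, for a physical reason: a propagating wave's spatial wavelength is
speed × period, and at the 2 µm pixel scale a slower beat keeps slow
waves spatially resolvable.

Three generators build on the kernel, each returning its object plus a
ground-truth record sufficient to reproduce it:

* `generate_trace_set()` — per-ROI beat trains with i.i.d. Gaussian
  per-ROI-per-beat timing jitter and white intensity noise. Raw
  intensities are `baseline * (1 + signal)`, so `noise_sd` is in ΔF/F0
  units and SNR = amplitude / noise_sd. Every injected timing offset is
  recorded, making the synchronicity statistic testable against the
  exact injected sample.
* `generate_wave_movie()` — per-pixel activation delays set the
  propagation pattern: zero (synchronous), a linear function of
  position (plane wave at a given speed and direction), or radial
  distance from a centre (source; a sink is the time-reversed radial
  ordering, i.e. a converging wave). Frames are blurred by a Gaussian
  optical PSF (default σ = 1 px). The PSF is not cosmetic: a 5 µm/s
  wavefront rises over ~1 px, and without optical blur the rendered
  scene is spatially aliased in a way no real microscope produces —
  gradient-based flow estimation on such a scene fails with coherent
  but wrong answers.
* `generate_motion_movie()` — a static blurred-noise texture warped by
  a radial strain towards the image centre, following a smooth periodic
  pulse: an inward (contraction) stroke over `contraction_fraction` of
  the beat, an outward (relaxation) stroke over the rest. Equal
  displacement in less time makes contraction faster than relaxation
  when that fraction is below one half. The exact per-frame mean pixel
  speed is part of the ground truth.

All generators are bit-deterministic given their seed.

What the generators deliberately omit: photobleaching, indicator
binding kinetics, cell-scale texture in the calcium movies, occlusions
and out-of-plane motion in the motion movies, and any electrical
artifact. Passing recovery tests on these movies therefore shows the
*estimators* are correct and calibrated on clean, well-sampled input;
it does not certify performance on low-SNR or drifting recordings.

## Trace analysis: ΔF/F0, peaks, FWHM, τ, TPA-MAD

`extract_traces()` tiles a movie into a rectangular ROI grid (default
8×8; the field-of-view and ROI size of the original recordings are not
published, so this is a package choice) and takes spatial means.
ΔF/F0 uses $F_0$ = 10th percentile of each ROI's series — robust when
beats occupy a minority of frames — making every downstream metric
invariant to detector gain.

Peak detection is plain local-maxima filtering by topographic
prominence (default 0.2 ΔF/F0; use ~half the expected amplitude for
noisy traces) and minimum separation (default 250 ms). Peak times are
frame-accurate: at 20 frames/s that is 50 ms granularity, which also
bounds how finely the synchronicity statistic can resolve.

Per-peak FWHM interpolates the two half-height crossings nearest the
peak linearly between bracketing frames; a flank that never falls below
half height (clipped transient) yields `NA`.

The decay constant is fit on the window from the peak to the earlier of
the return to 10% of peak height and the next beat's onset (the trough
between peaks). The model is $A e^{-t/\tau} + C$: the baseline term $C$
matters because percentile-based normalization leaves a small negative
offset when traces never fully return to baseline between beats, and
an offset-free fit is then biased several percent even without noise.
$A$ and $C$ are linear and profiled out in closed form; $\tau$ comes
from bounded one-dimensional minimization of the residual sum of
squares, which is deterministic and cannot fail to converge. Two guards
flag unusable windows: a variance-stabilized log-domain fit must show a
negative slope, and $\hat\tau$ above twice the window span is declared
unidentifiable (such a decay is indistinguishable from a constant over
the window). At SNR 10 the per-peak $\hat\tau$ distribution is
right-skewed, so condition-level summaries use the median over peaks —
consistent with the robust, outlier-trimmed aggregation common in this
assay.

Synchronicity is the time-of-peak-arrival median absolute deviation
(TPA-MAD): beats are matched across ROIs by nearest-neighbour
assignment to reference beat times (per-beat medians over the ROIs with
the modal peak count) within half the median inter-beat interval; for
each matched beat the **raw** MAD of arrival times across ROIs is
computed (no 1.4826 Gaussian consistency factor — the statistic is
reported as a deviation in ms, not a σ estimate), and the result is the
median over beats. Identical ROIs give 0; constructed offsets of
{−50, 0, +50} ms give exactly 50 ms. Because peak times are
frame-accurate, injected jitter at or below one frame period is
quantized; quantitative agreement with the injected offset sample is
only expected (and only tested) for jitter well above 50 ms.

## Wave velocimetry: Horn–Schunck flow and circular statistics

Movies destined for flow analysis are preprocessed with a 3×3 spatial
median per frame (computed exactly for all pixels at once with a
median-of-9 sorting network) and a zero-phase temporal low-pass below
1 Hz. The low-pass is realized spectrally: the forward–backward cascade
of a second-order Butterworth has squared-magnitude response
$1/(1+(f/f_c)^4)$ and zero phase, and applying exactly that response on
a mirror-extended series gives the same steady-state behaviour as
forward–backward recursive filtering without its end transients —
which, on 120-frame clips, otherwise corrupt enough frame pairs to
inflate pooled flow magnitudes severalfold. Zero phase matters because
peak-arrival times feed the synchronicity statistic. A cutoff below the
beating band strongly shapes flow magnitudes; it is the convention for
this assay, and it is configurable.

`horn_schunck()` minimizes the classical global functional — squared
brightness-constancy residual $(E_x u + E_y v + E_t)^2$ plus $\alpha^2$
times the squared flow gradient — with the standard 2×2×2-cube
derivative estimates and Jacobi iteration over the 8-neighbour weighted
average (iterated in compiled code). Defaults $\alpha = 1$,
`n_iter = 200`, `tol = 1e-4` are conventional for intensity-scale
images; they are hyperparameters, and correctness is established by
recovery tests rather than by any fixed constant. Two numerical
caveats are documented behaviours: Jacobi iteration propagates flow
into low-gradient regions slowly (isolated compact objects need more
iterations or smaller α than a full-field wave), and the derivative
stencil sits on a half-pixel-offset cube corner, so 90° grid rotation
is equivariant to ~0.5% rather than exactly.

`compute_flow_sequence()` runs every consecutive frame pair and masks
out pixels whose temporal ΔF/F0 range is below 20% of the median
per-pixel range (inactive tissue). `flow_summary()` pools masked
vectors over all frame pairs — a per-sequence summary — and reports the
mean vector magnitude in µm/s (pixels/frame × pixel size × frame rate)
and the circular statistics of the vector phase
$\theta = \mathrm{atan2}(v, u)$: circular mean, and circular variance
$1 - \|\mathrm{mean}(e^{i\theta})\|$, 0 for perfectly aligned flow and
1 for uniformly dispersed directions. Phase statistics are unweighted
by magnitude but exclude vectors below a floor (default: the 10th
percentile of pooled magnitudes) so near-zero noise vectors between
wavefront transits do not dilute directionality. `rose_histogram()`
bins the same phases for polar rose plots.

On seeded plane waves at 5–20 µm/s (2 µm pixels, 20 frames/s) the
pipeline recovers speed within a few percent, direction within ~6°, and
circular variance below 0.1; matched source/sink movies give circular
variance above 0.9 — an order of magnitude higher, the signature of
multidirectional propagation.

## Contractility

`velocity_trace()` reduces each frame pair of a phase-contrast movie to
the whole-frame mean flow magnitude in µm/s ("normalized to image
length scales" via the pixel size). Frames are first rescaled to unit
dynamic range, making the measurement invariant to illumination offset
and gain; consequently the smoothness weight is expressed relative to
unit contrast, and the default here is α = 0.1 — dense texture makes
brightness constancy informative at nearly every pixel, and heavier
smoothing biases textured-motion speed towards zero.

`contraction_relaxation_metrics()` detects speed peaks (default
prominence: a quarter of the trace maximum), pairs consecutive peaks
into beats, and labels the first of each pair contraction and the
second relaxation — monolayer recoil follows contraction. A trailing
unpaired peak is dropped with a warning. Optical flow slightly
underestimates true stroke speeds near the strain extremes, so recovery
against the generator truth is asserted at the tens-of-percent level,
while symmetric beats reproduce contraction ≈ relaxation within a few
percent.

## Orchestration and reproducibility

`run_pipeline()` executes a list of named conditions — each optionally
carrying a regimen block, a calcium-movie or trace-set block, and a
motion block — writing per-condition CSV/JSON artifacts and a
consolidated report whose header records the configuration hash and
seed. Configurations are validated before any computation (fail-fast,
no partial outputs), and per-stage seeds are derived deterministically
from the global seed (`seed + 101 * condition + stage`), so identical
configuration and seed give byte-identical outputs and any stage can be
regenerated in isolation. The package's interface is R functions plus
the repository's `scripts/acceptance.R`; no shell CLI is shipped, as
the intended users drive analyses from R.

The bundled six-condition demo (`inst/extdata/demo_config.json`)
mirrors the study layout — three static regimens, two ramped regimens,
one unstimulated control — at desk scale: 48×48-pixel movies, 60–80
frames, wave speeds at the monolayer-conduction scale (100–260 µm/s) so
that ROI traces stay beat-resolved, with multidirectional (source)
patterns for the weakly coupled conditions and plane waves for the
dynamically stimulated ones. Test-suite simulations use 128×128×120
movies only where wave-recovery accuracy is itself under test, and
16-ROI × 8-beat trace sets for kinetics and synchronicity; these sizes
are the package's chosen study conditions.

## Known limitations

* Estimator validation rests on the generators above; none of the
  tests exercise bleaching, focus drift, or segmentation-worthy
  spatial heterogeneity.
* Horn–Schunck magnitude is biased low for displacements approaching a
  pixel per frame and for weakly textured regions; comparisons across
  conditions filmed identically are safer than absolute speeds.
* TPA-MAD resolution is one frame period; sub-frame synchronicity
  differences are invisible at 20 frames/s.
* The regimen twin models ideal electronics; electrode polarization,
  media impedance and delivered-current sensing are out of scope.
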