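---
title: "Detecting and photobleaching presynaptic calcium transients: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and photobleaching presynaptic calcium transients: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonca)
```

## The problem

Fluorescence imaging of single presynaptic boutons at 10 Hz shows three
distinguishable calcium signals: *evoked* transients time-locked to field
stimulation, rare *spontaneous* transients, and an elevated, noisy *baseline*
between transients. `boutonca` implements the quantification pipeline for such
recordings — event detection against a moving baseline, per-event kinetics,
baseline-level and noise quantification, epoch comparisons under treatments,
and use-dependent photobleaching/recovery analysis — together with a seeded
generative simulator of bouton fluorescence, so that every stage of the
pipeline can be exercised against ground truth without any recorded data.

## The generative model

A bouton's trace is

$$F(t) = F_0\Big(1 + u_E \textstyle\sum_e A_e\,k_e(t) + u_S \sum_s A_s\,k_s(t)
 + u_B\, b(t)\Big) + \varepsilon(t),$$

with $k(t) = \big(e^{-t/\tau_d} - e^{-t/\tau_r}\big)/\mathrm{peak}$ the
unit-peak difference-of-exponentials transient kernel, $\varepsilon$ Gaussian
read noise, and $u_E, u_S, u_B \in [0,1]$ the unbleached fractions of the
three sensor pools (all 1 without photobleaching). Evoked events occur at
stimulus times with probability `p_evoked`; spontaneous events are a
homogeneous Poisson process; amplitudes are lognormal. The baseline $b(t)$ is
a shot-noise superposition: Poisson micro-transients at `shot_rate` per
second, `shot_amp` dF/F each, mimicking stochastic single voltage-gated
channel openings. By Campbell's theorem its mean is
`shot_rate * shot_amp * kernel_area` (`baseline_occupancy()`), and it
contributes both an elevated mean level and extra trace variance — so a
treatment that lowers `shot_rate` lowers the baseline level *and* the noise
SD together, the diagnostic signature the pipeline must recover. High-K+
epochs drive all three classes at saturating duty and are used to localize
active boutons.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `sampling_rate` | 10 Hz | acquisition rate |
| `p_evoked` | 0.95 | probability of an evoked transient per stimulus |
| `A_evoked`, `A_spont` | 1.0, 0.5 dF/F | median event amplitudes (CV 0.3) |
| `tau_rise_evoked`, `tau_decay` | 0.05, 1.0 s | evoked kernel |
| `tau_rise_spont`, `tau_decay_spont` | 0.5, 0.55 s | spontaneous kernel |
| `lambda_spont` | 0.1 /min | spontaneous rate of an active bouton |
| `shot_rate`, `shot_amp` | 250 /s, 0.0012 dF/F | baseline micro-openings |
| `F0`, `sigma_noise` | 100, 3 F units | resting fluorescence, read noise |
| `k_bleach` | 0.017 /s | bleach rate of a fluorescent sensor |
| `k_exchange` | 0.01 /min | reservoir exchange rate |

The kinetic constants encode a slow sensor (measured decay about 1 s) and are
the product of two deliberate calibrations. First, spontaneous transients
rise visibly more slowly than evoked ones; at 10 Hz with 3-point smoothing a
rise-constant contrast only survives measurement if the kernels differ
strongly (dense 20–80% rise 0.21 s vs 0.05 s with these defaults). Second,
the *measured* decay of the two classes should be similar even though their
rise differs. A decay constant shared between classes fails this: the
difference-of-exponentials rise tail contaminates the post-peak fit and makes
the slow-rising class's fitted decay ~25% slower. `tau_decay_spont` is
therefore calibrated through the full measurement operator (detection,
isolated event-triggered averaging, exponential fit) so both classes fit to
the same decay within a few percent.

The spontaneous rate (0.1/min for an active bouton) together with a cohort
silent fraction of 0.9 places cohort-mean detected frequencies at the low end
of the observed 0.01–0.05 events/ROI/min range and is also the only regime
consistent with use-dependent bleaching sparing spontaneous transients (see
below). The glutamate-sensor preset (`iglusnfr_config()`) uses faster kernels
(decay 0.3 s), quantal amplitudes similar across classes and a spontaneous
rate of 2 events/min — the upper end of miniature-release rates reported for
dissociated hippocampal synapses; spontaneous glutamate events are thus an
order of magnitude more frequent than spontaneous calcium transients, and no
boutons are silent by default.

`pool_fractions` are bookkeeping weights of sensor mass per pool, used for
conservation diagnostics; amplitudes are parameterized directly, so the
fractions do not rescale the trace.

## Detection

The standard procedure for such recordings is followed step by step:

1. **Background subtraction** (`subtract_background`): a least-squares line
   through the rolling 10th-percentile series (30-s blocks) is removed as
   slope only; the absolute level is kept so baseline quantification remains
   meaningful.
2. **Smoothing** (`smooth_trace`): one pass of a centered 3-frame moving
   average ("smoothed at up to three points"; the window is a parameter).
3. **Moving baseline** (`moving_baseline`): trailing 4-s mean, excluding the
   current frame, expanding at the trace start.
4. **Noise SD** (`estimate_noise_sd`): robust SD (MAD × 1.4826) of
   `trace − baseline` with detected events and 1 s after each stimulus
   masked; the pipeline runs two passes (provisional SD → mask → final SD).
5. **Events** (`detect_events`): an event starts where the smoothed trace
   exceeds the baseline by 3 SD, the baseline is frozen at its onset value
   for the event's duration (a trailing mean would otherwise absorb the event
   and truncate its amplitude), and the event ends below 1 SD above the
   frozen baseline. Onsets closer than 0.5 s merge. Events whose onset falls
   in `[t_stim, t_stim + 0.3 s)` are evoked (closed left, open right — the
   deterministic boundary choice); evoked events never count toward
   spontaneous frequencies.

Two scope choices deserve emphasis:

* **Which SD?** The threshold SD is estimated from the *unsmoothed* detrended
  residuals while detection runs on the smoothed trace. This makes the
  effective threshold ≈ 3√3 smoothed-noise SDs for white noise, and the
  false-positive floor of the rule correspondingly small (measured below
  0.02 events/ROI/min on pure noise, ~0.003/min at the default trace
  statistics). Estimating the SD on the smoothed residuals instead would
  yield a floor of order 0.1–0.5 events/ROI/min — larger than the
  spontaneous rates being measured and incompatible with ~90% of synapses
  showing no events in 10 minutes. The floor is nonzero and is checked
  against a Monte-Carlo oracle of the identical rule in the test suite.
* **Baseline after an event.** The frozen baseline applies within the event
  extent only; afterwards the precomputed trailing mean resumes (event frames
  leave the window within 4 s).

## Kinetics

Per event: amplitude above the frozen baseline, in F units and dF/F; 20–80%
rise time with linear interpolation, crossings located backward from the
peak (the onset-side first crossing is noise-sensitive); decay as the τ of a
single-exponential least-squares fit from the peak over at most 2 s
(truncated at the next event), with time-to-half-amplitude ÷ ln 2 as the
fallback when the fit fails or diverges (fits with τ beyond 5× the window
are treated as failures). A peak at the trace end leaves decay undefined and
flagged.

Amplitudes are measured on the *unsmoothed* detrended trace (maximum over
the event extent): the 3-point average attenuates the fast evoked peak by
about 7%, while the raw maximum at the pipeline's working SNR is unbiased to
within ~2%. Rise and decay are fitted on the smoothed trace, where the
landmarks are stable. Per-event rise times at 10 Hz carry a measurement
floor of roughly one frame; class comparisons therefore use
`event_triggered_average()` — mean waveforms of isolated events aligned at
onset, the standard averaged-event view for class kinetics — and
`waveform_kinetics()` on the average.

## Photobleaching model

Only fluorescent sensors bleach. Each pool carries a fluorescent duty cycle:
stimulated epochs give the evoked pool
`p_evoked × kernel_area / stimulus_interval` ≈ 0.11; the spontaneous pool's
duty is `lambda_spont × kernel_area` ≈ 10⁻³ (the basis of its resistance);
the baseline pool rests at its shot-noise occupancy ≈ 0.32; high-K+ epochs
saturate all three. The unbleached fractions follow

$$\dot u_p = -k_\mathrm{bleach}\,\mathrm{duty}_p\,u_p
  + k_\mathrm{exchange}(1-u_p),$$

updated with the exact exponential solution per epoch (no Euler drift, so
fractions stay in [0,1] for any step and mass is conserved when exchange is
off). Exchange with an infinite unbleached reservoir acts in every epoch;
with the default 0.01/min, recovery after a maximal bleach reaches ~95% by
5 h, and the closed form $u(t) = 1-(1-u_0)e^{-k_x t}$ is the test oracle for
the measured recovery curve. The bleach-illumination duty within a bleach
epoch (continuous vs pulsed) is exposed as `bleach_illum_duty` (default 1 =
continuous).

The constants `k_bleach = 0.017`/s and `lambda_spont = 0.1`/min were chosen
jointly from the closed form: a 30-min stimulated bleach must drive the
evoked pool's exposure to ≈ 3.4 (likelihood collapses) while the spontaneous
pool's exposure stays below ≈ 0.09 (its amplitude ratio stays within the
susceptibility margin). Because exposure ratios equal duty ratios, a
spontaneous rate much above ~0.1/min would make spontaneous transients
measurably bleachable at rest — so the reported resistance of spontaneous
transients itself constrains the plausible per-bouton rate, consistent with
the interpretation that their resistance reflects their low frequency.

Susceptibility (`bleach_susceptibility`) compares each protocol's
after/before ratio per metric against a matched no-bleach control and calls a
metric susceptible when it falls more than 10 percentage points below the
control (the margin is a parameter; experimental analyses of this kind rely on
significance tests, which are out of scope here — the fixed margin makes the matrix
deterministic). Controls are *matched*: control sessions reuse the bleach
sessions' seeds, and the simulator draws events from per-epoch substreams, so
both arms see identical event and noise realizations in the shared epochs and
the bleach-minus-control differences isolate the bleaching effect. Without
this pairing, deciding the spontaneous-class cells at 0.01–0.05
events/ROI/min would require cohorts of thousands of ROI-hours.

The trace-SD metric sits close to the margin by construction: read noise
does not bleach, so a full baseline bleach lowers the residual SD only by
the shot-noise share (ratio ≈ 0.9 at the defaults).

## Epoch comparisons and aggregation

`compare_epochs()` implements both normalization conventions: `gcamp`
divides each bouton's after-value by the coverslip average of before-values
(spontaneous transients are too rare to normalize per synapse), `iglusnfr`
normalizes synapse by synapse so every before-value maps to 1 (zero
denominators are excluded and counted). The synapse-by-synapse frequency
ratio is upward-biased at small event counts (≈ +4 points on a 69% effect at
20 events per epoch, from E[1/N] > 1/E[N]); this is a property of the
convention itself and is retained. `aggregate_coverslips()` averages per
coverslip — the replicate unit for statistics — and reports spontaneous
frequency both over all synapses (silent ones at 0) and over active synapses
only. Inferential statistics are deliberately not reimplemented; the tables
export cleanly to any stats tool.

## What the simulator does and does not emulate

Emulated: 10-Hz traces of sparse boutons; stimulus-locked evoked transients
at 10-s intervals; rare Poisson spontaneous transients; shot-noise baseline;
epoch-structured protocols (before → bleach/treatment → after → recovery);
use-dependent bleaching with slow reservoir exchange; treatments as parameter
scalings (channel blockade → `p_evoked` and `shot_rate`; ryanodine-receptor
block → `lambda_spont`; vehicle → identity); optional rendering of image
stacks (2-D Gaussian puncta, Poisson photon noise, Gaussian read noise) for
the ROI-extraction stage, at 0.25 μm/px with a 0.5 μm PSF σ (only the 3-μm
ROI diameter is a fixed convention of the analysis).

Not emulated: sensor binding kinetics and buffering (kernels are
phenomenological); spatial nanodomain geometry (pools are abstract
compartments); axonal structure or inter-bouton correlations; stage drift
and motion (the 3-μm ROI slack is the only drift allowance — a recorded
limitation of the ROI stage); recurrent network activity. Passing tests
therefore demonstrate that the pipeline recovers planted effects under this
idealized noise model, not that it is robust to motion artifacts,
out-of-focus drift, or non-stationary noise in real recordings.

## Numerical choices and degenerate inputs

Exact exponential bleach updates; kernel tails truncated where the kernel
falls below 10⁻³ of peak; the shot-noise process is warmed up for one kernel
length before each epoch so it is stationary from the first frame; puncta
detection smooths with a σ = 1 px Gaussian before taking local maxima
(threshold mean + 2 SD; both defaults are explicit because no canonical values exist
for this step), accepts maxima greedily in descending intensity with a 3-μm
separation, and breaks ties in row-major pixel order; coordinates are
0-based, origin top-left. Degenerate inputs fail loudly: a constant trace has
σ = 0 and is rejected with a diagnostic; a flat image yields no puncta (not
an error); schedules must tile `[0, duration]`; fractions and probabilities
are range-checked at construction.

## Problem sizes

The test suite runs the detector–reference equivalence on 1,000 random 60-s
traces, the false-positive comparison on 2 × 500 traces, planted-event
recovery on 200 seeds, the susceptibility matrix on 200 sessions × 4 arms,
and the recovery curve on 4 durations × 30 sessions; the planted-effect
treatment experiments use 300 ROIs × 10-min epochs (spontaneous) and 100
ROIs × 60 stimuli (evoked). These sizes put Monte-Carlo error comfortably
inside the assertion bands while keeping a full run in a few minutes on one
CPU.

## Known limitations

* Detected onsets lag true onsets by up to ~1 frame for events near the
  5 SD range (the threshold is crossed on the rising limb); amplitude and
  likelihood metrics are insensitive to this, but absolute latencies should
  not be over-interpreted at 10 Hz.
* The false-positive floor, while small, is nonzero; detected frequencies at
  or below ~0.005 events/ROI/min are at the floor's scale.
* The susceptibility margin (10 points) is a stand-in for the significance
  tests such experiments normally rely on; borderline metrics (trace SD under
  partial bleach) can flip with a different margin.
* Recovery measurements immediately after a maximal bleach are
  detection-censored (only supra-threshold events are seen), so the measured
  amplitude ratio at t = 0 sits above the true unbleached fraction; the
  closed-form comparison applies once amplitudes clear the threshold.
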